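# broom-style accessors for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained VAE
#'
#' @param x a `benthic_vae`.
#' @param ... unused.
#' @return the per-epoch loss history as a tibble
#'   (`epoch, recon, kl, loss`).
#' @export
tidy.benthic_vae <- function(x, ...) x$loss_history

#' @rdname tidy.benthic_vae
#' @return `glance()`: one-row tibble with architecture and final loss.
#' @export
glance.benthic_vae <- function(x, ...) {
  last <- x$loss_history[nrow(x$loss_history), ]
  tibble::tibble(latent_dim = x$config$latent_dim,
                 hidden_dim = x$config$hidden_dim,
                 epochs = x$config$epochs,
                 final_loss = last$loss, final_recon = last$recon,
                 final_kl = last$kl)
}

#' Tidy an isolation forest
#'
#' @param x an `isolation_forest`.
#' @param ... unused.
#' @return tibble with one row per tree (`tree, n_nodes, n_leaves,
#'   max_depth`).
#' @export
tidy.isolation_forest <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$trees), function(i) {
    tr <- x$trees[[i]]
    depth <- integer(length(tr$leaf))
    for (j in seq_along(tr$leaf)) {
      if (!tr$leaf[j]) {
        depth[tr$left[j]] <- depth[j] + 1L
        depth[tr$right[j]] <- depth[j] + 1L
      }
    }
    tibble::tibble(tree = i, n_nodes = length(tr$leaf),
                   n_leaves = sum(tr$leaf), max_depth = max(depth))
  }))
}

#' @rdname tidy.isolation_forest
#' @return `glance()`: one-row tibble of forest hyperparameters.
#' @export
glance.isolation_forest <- function(x, ...) {
  tibble::tibble(n_trees = length(x$trees), subsample_size = x$psi,
                 contamination = x$config$contamination,
                 n_features = x$n_features,
                 height_limit = ceiling(log2(x$psi)))
}

#' Tidy a detection evaluation
#'
#' @param x a `detection_eval`.
#' @param ... unused.
#' @return long tibble `metric, value` (percentages; `NA` for empty
#'   strata).
#' @export
tidy.detection_eval <- function(x, ...) {
  tibble::tibble(metric = names(x$metrics), value = unname(x$metrics))
}

#' @rdname tidy.detection_eval
#' @return `glance()`: one-row tibble of the headline metrics.
#' @export
glance.detection_eval <- function(x, ...) {
  tibble::as_tibble(as.list(x$metrics))
}
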