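#' Variational autoencoder configuration
#'
#' A compact VAE learns an unsupervised representation of superpixel
#' patches; its posterior mean serves as the feature vector for anomaly
#' scoring. Patches are average-pooled to `input_side x input_side x 3`
#' before the dense encoder — colour and coarse morphology, which is what
#' separates fauna from sediment and nodules, survive pooling, and the
#' resulting net trains on a CPU in minutes.
#'
#' @param latent_dim latent dimensionality (>= 2; default 100). The
#'   feature dimension trades compactness against fidelity and should be
#'   tuned per dataset.
#' @param patch_size expected side of input patches, pixels.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size (> 0).
#' @param hidden_dim width of the single hidden layer on each side.
#' @param input_side pooled patch side fed to the dense net.
#' @param seed integer seed controlling init, shuffling and sampling.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 100, patch_size = 64, epochs = 15,
                       batch_size = 64, learning_rate = 1e-3,
                       hidden_dim = 128, input_side = 16, seed = 1) {
  latent_dim <- check_count(latent_dim, "latent_dim", min = 2)
  epochs <- check_count(epochs, "epochs", min = 1)
  batch_size <- check_count(batch_size, "batch_size", min = 1)
  check_number(learning_rate, "learning_rate", min = 0, closed_min = FALSE)
  structure(list(latent_dim = latent_dim, patch_size = patch_size,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, hidden_dim = hidden_dim,
                 input_side = check_count(input_side, "input_side", min = 2),
                 seed = as.integer(seed)),
            class = "vae_config")
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' `KL = 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` per sample; this is
#' the regularisation term of the VAE loss and is non-negative for every
#' posterior.
#'
#' @param mu,logvar numeric vectors (one sample) or matrices
#'   (samples x dims) of posterior means and log-variances.
#' @return numeric vector of per-sample KL values.
#' @export
kl_divergence <- function(mu, logvar) {
  if (is.matrix(mu)) {
    rowSums(0.5 * (mu^2 + exp(logvar) - 1 - logvar))
  } else {
    sum(0.5 * (mu^2 + exp(logvar) - 1 - logvar))
  }
}

vae_forward_mu <- function(params, X) {
  h1 <- relu(sweep_add(X %*% params$W1, params$b1))
  sweep_add(h1 %*% params$Wmu, params$bmu)
}

#' Train the patch VAE
#'
#' Minimises reconstruction error plus the KL regulariser
#' ([kl_divergence()]) with Adam, using the reparameterisation
#' `z = mu + sigma * eps` during training only. The reconstruction term is
#' the per-sample sum of squared pixel errors on `[0,1]` RGB, which keeps
#' it commensurate with the summed KL term so the posterior stays
#' informative.
#'
#' @param patches tibble from [extract_patches()] (or a list of
#'   `patch_size x patch_size x 3` arrays).
#' @param config a [vae_config()]; needs at least `batch_size` patches.
#' @return object of class `benthic_vae` with the trained weights and a
#'   `loss_history` tibble (`epoch, recon, kl, loss`, epoch means).
#'   Training fails with an error naming the epoch if the loss goes
#'   non-finite.
#' @export
train_vae <- function(patches, config = vae_config()) {
  if (!inherits(config, "vae_config")) {
    stop("`config` must be created by vae_config()", call. = FALSE)
  }
  X <- patches_to_matrix(patches, config$input_side)
  if (nrow(X) < config$batch_size) {
    stop(sprintf("need at least `batch_size` (%d) patches, got %d",
                 config$batch_size, nrow(X)), call. = FALSE)
  }
  if (any(X < 0) || any(X > 1)) {
    stop("patch pixel values must lie in [0, 1]", call. = FALSE)
  }
  D <- ncol(X); H <- config$hidden_dim; L <- config$latent_dim
  n <- nrow(X)

  with_seed(derive_seed(config$seed, "train_vae"), {
    params <- list(
      W1 = nn_init_matrix(D, H), b1 = numeric(H),
      Wmu = nn_init_matrix(H, L), bmu = numeric(L),
      Wlv = nn_init_matrix(H, L) * 0.01, blv = numeric(L),
      W2 = nn_init_matrix(L, H), b2 = numeric(H),
      W3 = nn_init_matrix(H, D), b3 = numeric(D))
    state <- adam_init(params)
    history <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_recon <- ep_kl <- 0; ep_n <- 0
      for (s in starts) {
        batch <- idx[s:min(s + config$batch_size - 1, n)]
        xb <- X[batch, , drop = FALSE]
        nb <- nrow(xb)

        a1 <- sweep_add(xb %*% params$W1, params$b1); h1 <- relu(a1)
        mu <- sweep_add(h1 %*% params$Wmu, params$bmu)
        lv <- pmin(pmax(sweep_add(h1 %*% params$Wlv, params$blv), -10), 10)
        eps <- matrix(stats::rnorm(nb * L), nb, L)
        z <- mu + exp(lv / 2) * eps
        a2 <- sweep_add(z %*% params$W2, params$b2); h2 <- relu(a2)
        logits <- sweep_add(h2 %*% params$W3, params$b3)
        xhat <- sigmoid(logits)

        recon_i <- rowSums((xhat - xb)^2)
        kl_i <- kl_divergence(mu, lv)
        batch_kl <- mean(kl_i)
        stopifnot(batch_kl >= -1e-8) # KL is non-negative by construction
        loss <- mean(recon_i) + batch_kl
        if (!is.finite(loss)) {
          stop(sprintf("VAE training diverged at epoch %d (non-finite loss)",
                       epoch), call. = FALSE)
        }

        dlogits <- (2 * (xhat - xb)) * xhat * (1 - xhat) / nb
        gW3 <- crossprod(h2, dlogits); gb3 <- colSums(dlogits)
        da2 <- (dlogits %*% t(params$W3)) * (a2 > 0)
        gW2 <- crossprod(z, da2); gb2 <- colSums(da2)
        dz <- da2 %*% t(params$W2)
        dmu <- dz + mu / nb
        dlv <- dz * eps * exp(lv / 2) * 0.5 + 0.5 * (exp(lv) - 1) / nb
        gWmu <- crossprod(h1, dmu); gbmu <- colSums(dmu)
        gWlv <- crossprod(h1, dlv); gblv <- colSums(dlv)
        da1 <- (dmu %*% t(params$Wmu) + dlv %*% t(params$Wlv)) * (a1 > 0)
        gW1 <- crossprod(xb, da1); gb1 <- colSums(da1)

        upd <- adam_step(params,
                         list(W1 = gW1, b1 = gb1, Wmu = gWmu, bmu = gbmu,
                              Wlv = gWlv, blv = gblv, W2 = gW2, b2 = gb2,
                              W3 = gW3, b3 = gb3),
                         state, config$learning_rate)
        params <- upd$params; state <- upd$state

        ep_recon <- ep_recon + sum(recon_i)
        ep_kl <- ep_kl + sum(kl_i)
        ep_n <- ep_n + nb
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, recon = ep_recon / ep_n, kl = ep_kl / ep_n,
        loss = (ep_recon + ep_kl) / ep_n)
    }

    structure(list(params = params, config = config,
                   loss_history = dplyr::bind_rows(history)),
              class = "benthic_vae")
  })
}

#' Extract features from patches
#'
#' Deterministic inference: each patch is encoded to the posterior mean
#' `mu` (no sampling), giving reproducible features for downstream
#' anomaly scoring.
#'
#' @param vae a trained [train_vae()] model.
#' @param patches tibble from [extract_patches()] or list of arrays;
#'   patch side must match the training `patch_size`.
#' @return numeric feature matrix (`n_patches x latent_dim`) with patch
#'   ids as row names; no non-finite entries.
#' @export
encode_patches <- function(vae, patches) {
  if (!inherits(vae, "benthic_vae")) {
    stop("`vae` must be a trained benthic_vae", call. = FALSE)
  }
  plist <- if (is.data.frame(patches)) patches$patch else patches
  sides <- vapply(plist, function(p) dim(p)[1], numeric(1))
  if (any(sides != vae$config$patch_size)) {
    stop(sprintf("patch side %s does not match the encoder's patch_size %d",
                 paste(unique(sides[sides != vae$config$patch_size]),
                       collapse = ","),
                 vae$config$patch_size), call. = FALSE)
  }
  X <- patches_to_matrix(patches, vae$config$input_side)
  f <- vae_forward_mu(vae$params, X)
  rownames(f) <- if (is.data.frame(patches)) patches$patch_id
                 else names(plist) %||% as.character(seq_len(nrow(f)))
  stopifnot(all(is.finite(f)))
  f
}

#' Two-dimensional PCA projection of a feature matrix
#'
#' Projects features onto the top two principal components of the
#' column-centred matrix, for visual inspection of the background /
#' anomaly structure of the feature space.
#'
#' @param features numeric matrix (`n >= 3` rows), e.g. from
#'   [encode_patches()].
#' @return object of class `patch_projection`: list with `scores`
#'   (tibble `patch_id, PC1, PC2`) and `explained_variance`
#'   (non-increasing fractions of total variance, length 2).
#' @export
project_2d <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3) {
    stop("`features` needs at least 3 rows", call. = FALSE)
  }
  centred <- scale(features, center = TRUE, scale = FALSE)
  total_var <- sum(centred^2) / (nrow(features) - 1)
  if (total_var <= 0) {
    stop("degenerate input: feature matrix has rank 0 after centering",
         call. = FALSE)
  }
  p <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = 2)
  ev <- p$sdev[1:2]^2 / sum(p$sdev^2)
  structure(
    list(scores = tibble::tibble(
           patch_id = rownames(features) %||%
             as.character(seq_len(nrow(features))),
           PC1 = p$x[, 1], PC2 = p$x[, 2]),
         explained_variance = ev),
    class = "patch_projection")
}
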