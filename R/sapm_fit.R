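# internal: system matrices from a named weight vector.
# A[target, source] over regions; M[target, latent] over latent links.
# Latent-link weights absent from `db` default to 1.
.net_matrices <- function(net, db) {
  ab <- net$regions$abbrev
  R <- length(ab)
  A <- matrix(0, R, R, dimnames = list(ab, ab))
  con <- net$connections
  if (nrow(con)) {
    lab <- edge_label(con$source, con$target)
    w <- db[lab]
    w[is.na(w)] <- 0
    A[cbind(con$target, con$source)] <- w
  }
  lnames <- vapply(net$latents, `[[`, character(1), "name")
  M <- matrix(0, R, length(lnames), dimnames = list(ab, lnames))
  for (l in net$latents) {
    w <- db[edge_label(l$name, l$targets)]
    w[is.na(w)] <- 1
    M[cbind(l$targets, l$name)] <- w
  }
  list(A = A, M = M)
}

# internal: coerce latents (matrix with rownames, or list of
# list(name, series)) to an L x V matrix in network latent order
.latent_matrix <- function(net, latents) {
  lnames <- vapply(net$latents, `[[`, character(1), "name")
  if (is.list(latents) && !is.data.frame(latents) && is.null(dim(latents))) {
    nm <- vapply(latents, `[[`, character(1), "name")
    L <- do.call(rbind, lapply(latents, `[[`, "series"))
    rownames(L) <- nm
  } else L <- as.matrix(latents)
  if (is.null(rownames(L))) rownames(L) <- lnames[seq_len(nrow(L))]
  L[lnames, , drop = FALSE]
}

#' Deterministic forward model of network signaling
#'
#' Solves the summed-input model `O(t) = A O(t) + M L(t)` exactly, i.e.
#' `O = (I - A)^-1 M L`, where `A[r, s] = db["s->r"]` holds inter-region
#' weights and `M` the latent-link weights.  A region's modeled BOLD
#' response is the sum of its weighted inputs, which is identically its
#' output signaling under the model convention.
#'
#' @param net a `sapm_network`.
#' @param db named weight vector (`"SRC->TGT"`); latent-link entries
#'   (`"int1->C6RD"`) default to 1 when absent.
#' @param latents latent signals: matrix (latents x volumes, rownames =
#'   latent names) or list of `list(name=, series=)`.
#' @return matrix regions x volumes (rownames = region abbrevs).
#' @export
forward_model <- function(net, db, latents) {
  mats <- .net_matrices(net, db)
  L <- .latent_matrix(net, latents)
  rad <- max(Mod(eigen(mats$A, only.values = TRUE)$values))
  if (rad >= 1)
    stop(sprintf("unstable network weights: spectral radius %.4f >= 1", rad),
         call. = FALSE)
  R <- nrow(mats$A)
  solve(diag(R) - mats$A, mats$M %*% L)
}

#' Fitting options for the SAPM estimator
#'
#' @param n_latent_basis number of discrete-cosine basis functions used to
#'   represent each latent time-course (`NULL` = free-form, one parameter
#'   per volume; see Details).  Default 12.
#' @param max_iter maximum alternating-least-squares iterations.
#' @param tol relative SSE convergence tolerance.
#' @param n_restarts random restarts (best total SSE kept).
#' @param seed RNG seed for restart initialization.
#' @details A latent with a single target region and a free-form
#'   time-course can absorb that region's residual exactly, which leaves
#'   the region's incoming connection weights unidentified.  The cosine
#'   basis restricts latents to smooth BOLD-like trajectories and keeps
#'   the estimator well-posed; `n_latent_basis = NULL` disables this.
#' @return list of options.
#' @export
sapm_fit_opts <- function(n_latent_basis = 12L, max_iter = 200L, tol = 1e-6,
                          n_restarts = 5L, seed = 1L) {
  list(n_latent_basis = n_latent_basis, max_iter = as.integer(max_iter),
       tol = tol, n_restarts = as.integer(n_restarts), seed = as.integer(seed))
}

# internal: zero-mean cosine basis, V x K, unit-norm columns
.cosine_basis <- function(V, K) {
  if (is.null(K) || K >= V) return(diag(V))
  v <- (seq_len(V) - 0.5) / V
  B <- vapply(seq_len(K), function(k) cos(pi * k * v), numeric(V))
  B <- sweep(B, 2, colMeans(B))
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

# internal: least squares with minimum-norm fallback for rank deficiency
.ls_solve <- function(X, y, warn_env = NULL) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    if (!is.null(warn_env) && !isTRUE(warn_env$warned)) {
      warning("rank-deficient source set; using minimum-norm solution",
              call. = FALSE)
      warn_env$warned <- TRUE
    }
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    as.numeric(beta)
  } else qr.coef(qx, y)
}

#' Fit the SAPM model to observed region time-courses
#'
#' Alternating least squares: (i) given the latent time-courses, each
#' region's observed series is regressed on the observed series of its
#' source regions plus its latent links, giving the signed connectivity
#' (DB) weights; (ii) given the weights, each latent's time-course is
#' re-estimated by least squares over its target-region residual system,
#' then re-centered and rescaled to zero-mean unit variance with the
#' scale absorbed into the latent-link weights.  Iterates until the
#' relative SSE change falls below `tol`; the best of `n_restarts`
#' random initializations is returned.  Sign convention: each latent's
#' weight onto its first declared target is non-negative.
#'
#' @param observed matrix regions x volumes (rownames = region abbrevs,
#'   all network regions present; >= 8 volumes).
#' @param net a `sapm_network`.
#' @param opts see [sapm_fit_opts()].
#' @return an object of class `sapm_fit`: named `db` vector over all
#'   connections (inter-region and latent links), `latents` (list of
#'   zero-mean unit-variance series), `r2_total`, `r2_by_region`,
#'   `n_iter`, `converged`, `sse`, plus the (centered) `observed` matrix.
#' @export
fit_sapm <- function(observed, net, opts = sapm_fit_opts()) {
  ab <- net$regions$abbrev
  observed <- as.matrix(observed)
  if (is.null(rownames(observed)) && nrow(observed) == length(ab))
    rownames(observed) <- ab
  if (!all(ab %in% rownames(observed)))
    stop("observed must have one row per network region", call. = FALSE)
  Y <- observed[ab, , drop = FALSE]
  if (!all(is.finite(Y))) stop("non-finite values in observed series",
                               call. = FALSE)
  V <- ncol(Y)
  if (V < 8) stop("need at least 8 volumes", call. = FALSE)
  Y <- Y - rowMeans(Y)

  con <- net$connections
  lnames <- vapply(net$latents, `[[`, character(1), "name")
  sources <- lapply(ab, function(r) con$source[con$target == r])
  names(sources) <- ab
  lat_of <- lapply(ab, function(r)
    lnames[vapply(net$latents, function(l) r %in% l$targets, logical(1))])
  names(lat_of) <- ab
  first_target <- vapply(net$latents, function(l) l$targets[1], character(1))
  names(first_target) <- lnames

  B <- .cosine_basis(V, opts$n_latent_basis)
  BtB <- crossprod(B)
  sst <- rowSums(Y^2)
  warn_env <- new.env(); warn_env$warned <- FALSE

  run_restart <- function(rs) {
    set.seed(opts$seed + rs - 1L)
    Lmat <- matrix(0, length(lnames), V, dimnames = list(lnames, NULL))
    for (j in seq_along(lnames)) {
      l0 <- as.numeric(B %*% stats::rnorm(ncol(B)))
      s <- stats::sd(l0)
      Lmat[j, ] <- if (s > 0) (l0 - mean(l0)) / s else l0
    }
    db <- stats::setNames(numeric(length(connection_labels(net, TRUE))),
                          connection_labels(net, TRUE))
    resid <- Y
    sse_prev <- Inf; n_iter <- 0L; converged <- FALSE
    repeat {
      n_iter <- n_iter + 1L
      # (i) per-region conditional least squares
      for (r in ab) {
        rnames <- c(sources[[r]], lat_of[[r]])
        if (!length(rnames)) { resid[r, ] <- Y[r, ]; next }
        X <- t(rbind(Y[sources[[r]], , drop = FALSE],
                     Lmat[lat_of[[r]], , drop = FALSE]))
        beta <- .ls_solve(X, Y[r, ], warn_env)
        db[edge_label(rnames, r)] <- beta
        resid[r, ] <- Y[r, ] - as.numeric(X %*% beta)
      }
      sse <- sum(resid^2)
      if (is.finite(sse_prev) &&
          abs(sse_prev - sse) <= opts$tol * max(sse_prev, .Machine$double.eps)) {
        converged <- TRUE; break
      }
      if (n_iter >= opts$max_iter) break
      sse_prev <- sse
      # (ii) latent update over target-region residual systems
      for (j in seq_along(lnames)) {
        lj <- lnames[j]
        tg <- net$latents[[j]]$targets
        m <- db[edge_label(lj, tg)]
        ej <- resid[tg, , drop = FALSE] +
          outer(as.numeric(m), Lmat[j, ])
        if (sum(m^2) < 1e-12) {
          # latent currently unused: seed it from its first target's residual
          cj <- .ls_solve(B, ej[1, ], NULL)
        } else {
          rhs <- crossprod(B, as.numeric(crossprod(ej, m)))
          cj <- solve(BtB * sum(m^2), rhs)
        }
        l_new <- as.numeric(B %*% cj)
        s <- stats::sd(l_new)
        if (s > 0) {
          Lmat[j, ] <- (l_new - mean(l_new)) / s
          db[edge_label(lj, tg)] <- m * s   # scale absorbed into weights
        }
      }
    }
    # sign convention: latent weight onto first declared target >= 0
    for (j in seq_along(lnames)) {
      lj <- lnames[j]
      key <- edge_label(lj, first_target[lj])
      if (db[key] < 0) {
        tg <- net$latents[[j]]$targets
        db[edge_label(lj, tg)] <- -db[edge_label(lj, tg)]
        Lmat[j, ] <- -Lmat[j, ]
      }
    }
    list(db = db, Lmat = Lmat, resid = resid, sse = sum(resid^2),
         n_iter = n_iter, converged = converged)
  }

  best <- NULL
  for (rs in seq_len(max(1L, opts$n_restarts))) {
    cand <- run_restart(rs)
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  r2 <- 1 - rowSums(best$resid^2) / pmax(sst, .Machine$double.eps)
  r2 <- pmin(pmax(r2, 0), 1)
  modeled <- ab[vapply(ab, function(r)
    length(sources[[r]]) + length(lat_of[[r]]) > 0, logical(1))]
  r2_total <- if (length(modeled)) {
    v <- 1 - sum(rowSums(best$resid[modeled, , drop = FALSE]^2)) /
      max(sum(sst[modeled]), .Machine$double.eps)
    min(max(v, 0), 1)
  } else 0
  structure(list(
    db = best$db,
    latents = lapply(seq_along(lnames), function(j)
      list(name = lnames[j], series = best$Lmat[j, ])),
    subregion_choice = NULL,
    r2_total = r2_total, r2_by_region = r2,
    n_iter = best$n_iter, converged = best$converged, sse = best$sse,
    observed = Y), class = "sapm_fit")
}

#' @export
print.sapm_fit <- function(x, ...) {
  cat(sprintf("sapm_fit: %d weights, r2_total = %.3f, %s after %d iterations\n",
              length(x$db), x$r2_total,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Select the best sub-region combination
#'
#' Chooses one sub-region per region to maximize the total variance
#' explained (`r2_total`) of [fit_sapm()].  For networks with at most
#' `exhaustive_max` regions every combination is enumerated (oracle
#' mode); otherwise greedy coordinate ascent from `combo_restarts`
#' starting combinations is used.  Ties break toward the lowest
#' sub-region index.
#'
#' @param candidates array regions x subregions x volumes (dimnames on
#'   the first margin = region abbrevs).
#' @param net a `sapm_network`.
#' @param opts fit options, see [sapm_fit_opts()].
#' @param combo_restarts random starting combinations for greedy ascent.
#' @param exhaustive_max maximum region count for exhaustive enumeration.
#' @return the best `sapm_fit`, with `subregion_choice` filled in.
#' @export
select_subregions <- function(candidates, net, opts = sapm_fit_opts(),
                              combo_restarts = 3L, exhaustive_max = 4L) {
  ab <- net$regions$abbrev
  stopifnot(length(dim(candidates)) == 3)
  if (is.null(dimnames(candidates)[[1]])) dimnames(candidates)[[1]] <- ab
  candidates <- candidates[ab, , , drop = FALSE]
  S <- dim(candidates)[2]
  R <- length(ab)

  fit_combo <- function(idx) {
    obs <- t(vapply(seq_len(R), function(i) candidates[i, idx[i], ],
                    numeric(dim(candidates)[3])))
    rownames(obs) <- ab
    fit_sapm(obs, net, opts)
  }
  cache <- new.env(parent = emptyenv())
  eval_combo <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fit_combo(idx)
    cache[[key]] <- f
    f
  }

  best_idx <- rep(1L, R); best_fit <- eval_combo(best_idx)
  if (R <= exhaustive_max) {
    grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), R)))
    for (g in seq_len(nrow(grid))) {
      idx <- as.integer(grid[g, ])
      f <- eval_combo(idx)
      if (f$r2_total > best_fit$r2_total + 1e-12) {
        best_fit <- f; best_idx <- idx
      }
    }
  } else {
    starts <- list(rep(1L, R))
    set.seed(opts$seed)
    for (s in seq_len(max(0L, combo_restarts - 1L)))
      starts[[s + 1L]] <- sample.int(S, R, replace = TRUE)
    for (idx in starts) {
      fit <- eval_combo(idx)
      repeat {
        improved <- FALSE
        for (i in seq_len(R)) for (s in seq_len(S)) {
          if (s == idx[i]) next
          trial <- idx; trial[i] <- s
          f <- eval_combo(trial)
          if (f$r2_total > fit$r2_total + 1e-12) {
            fit <- f; idx <- trial; improved <- TRUE
          }
        }
        if (!improved) break
      }
      if (fit$r2_total > best_fit$r2_total + 1e-12) {
        best_fit <- fit; best_idx <- idx
      }
    }
  }
  best_fit$subregion_choice <- stats::setNames(best_idx, ab)
  best_fit
}

#' Null reference distribution from phase-randomized surrogates
#'
#' Fits the model `n_null` times to phase-randomized surrogates of every
#' region series (independent surrogate seeds derived from `seed`),
#' collecting the fitted weights.  The resulting per-connection mean/SD
#' is the reference against which group-average DB values are tested.
#'
#' @param observed matrix regions x volumes.
#' @param net a `sapm_network`.
#' @param n_null number of surrogate fits (>= 2).
#' @param seed integer seed.
#' @param opts fit options.
#' @return object of class `sapm_null_reference` with `samples`
#'   (n_null x connections), `mean` and `sd` (named vectors).
#' @export
fit_null_reference <- function(observed, net, n_null = 25L, seed = 1L,
                               opts = sapm_fit_opts()) {
  if (n_null < 2) stop("n_null must be >= 2", call. = FALSE)
  ab <- net$regions$abbrev
  Y <- as.matrix(observed)[ab, , drop = FALSE]
  labs <- connection_labels(net, TRUE)
  samples <- matrix(NA_real_, n_null, length(labs),
                    dimnames = list(NULL, labs))
  for (i in seq_len(n_null)) {
    sur <- Y
    for (r in seq_len(nrow(Y)))
      sur[r, ] <- phase_randomize(Y[r, ], seed = seed + 7919L * i + r)
    f <- fit_sapm(sur, net, opts)
    samples[i, ] <- f$db[labs]
  }
  structure(list(samples = samples, mean = colMeans(samples),
                 sd = apply(samples, 2, stats::sd), n_null = n_null),
            class = "sapm_null_reference")
}

#' Derived D shares: per-source output apportionment
#'
#' The fraction of a source's total outgoing |DB| carried by each of its
#' outgoing connections.  Sources whose outgoing weights are all zero
#' get uniform shares.
#'
#' @param fit a `sapm_fit` (or named db vector).
#' @param net a `sapm_network`.
#' @return named vector of shares over all connections (per source,
#'   shares sum to 1).
#' @export
derived_D <- function(fit, net) {
  db <- if (inherits(fit, "sapm_fit")) fit$db else fit
  labs <- connection_labels(net, TRUE)
  src <- sub("->.*$", "", labs)
  shares <- stats::setNames(numeric(length(labs)), labs)
  for (s in unique(src)) {
    idx <- src == s
    tot <- sum(abs(db[labs[idx]]))
    shares[idx] <- if (tot > 0) abs(db[labs[idx]]) / tot else 1 / sum(idx)
  }
  shares
}

#' Decompose the modeled input signaling of a region
#'
#' Returns each source's weighted contribution `db[s->r] * O_s(t)` (with
#' `O_s` the observed source series used by the fit, and the fitted
#' latent time-courses for latent links), their sum — the modeled BOLD
#' response of the region — and the region's observed output series.
#'
#' @param fit a `sapm_fit`.
#' @param net the `sapm_network` the fit was computed on.
#' @param region region abbrev.
#' @return list with `contributions` (matrix sources x volumes),
#'   `total_input` (their exact sum) and `output` (observed series).
#' @export
signal_decomposition <- function(fit, net, region) {
  ab <- net$regions$abbrev
  if (!region %in% ab) stop("unknown region: ", region, call. = FALSE)
  con <- net$connections
  srcs <- con$source[con$target == region]
  lnames <- vapply(net$latents, `[[`, character(1), "name")
  lat <- lnames[vapply(net$latents, function(l) region %in% l$targets,
                       logical(1))]
  rows <- list()
  for (s in srcs)
    rows[[s]] <- fit$db[edge_label(s, region)] * fit$observed[s, ]
  for (l in lat) {
    series <- fit$latents[[match(l, lnames)]]$series
    rows[[l]] <- fit$db[edge_label(l, region)] * series
  }
  contributions <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0, ncol(fit$observed))
  total <- if (nrow(contributions)) colSums(contributions) else
    numeric(ncol(fit$observed))
  list(contributions = contributions, total_input = total,
       output = fit$observed[region, ])
}
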