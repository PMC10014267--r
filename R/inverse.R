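# Linear inverse operators, baseline-normalized source maps, ROI traces.

#' Build a linear inverse operator (wMNE or eLORETA)
#'
#' Weighted minimum-norm estimate: per-vertex depth weights
#' `w_v = ||l_v||^gamma` and kernel `K = W^-1 L' (L W^-1 L' + lambda^2 I)^+`.
#' eLORETA: weights from the fixed-point iteration
#' `w_v = sqrt(l_v' (L W^-1 L' + lambda^2 H)^+ l_v)` (H the common-average
#' projector), iterated until the relative weight change is below
#' `fp_tol`; the resulting kernel has exact localization for single point
#' sources in the noiseless, lambda -> 0 limit -- the property the source
#' maps rely on, and the reason the weighted family is used for deep
#' (cerebellar) sources where plain wMNE mislocalizes.
#'
#' `reg_lambda` is dimensionless: lambda^2 multiplies the mean diagonal of
#' `L W^-1 L'`, which makes the kernel scale-covariant in the lead field.
#'
#' @param fwd a `forward_model`.
#' @param method `"eLORETA"` (default) or `"wMNE"`.
#' @param reg_lambda regularization weight (dimensionless, default 0.05).
#' @param depth_gamma wMNE depth-weight exponent (default 1; 0 gives the
#'   classical unweighted MNE).
#' @param fp_tol,max_iter eLORETA fixed-point stopping rule.
#' @return object of class `inverse_operator` with `kernel`
#'   (vertices x channels), `method`, `reg_lambda`, `weights`.
#' @export
make_inverse <- function(fwd, method = c("eLORETA", "wMNE"),
                         reg_lambda = 0.05, depth_gamma = 1,
                         fp_tol = 1e-6, max_iter = 100) {
  method <- match.arg(method)
  L <- fwd$leadfield
  nc <- nrow(L); nv <- ncol(L)
  H <- diag(nc) - matrix(1 / nc, nc, nc)
  if (method == "wMNE") {
    w <- colSums(L^2)^(depth_gamma / 2)          # ||l_v||^gamma
    w <- w / mean(w)
    Lw <- sweep(L, 2, w, "/")                    # L W^-1 (W diagonal)
    A <- tcrossprod(Lw, L)                       # L W^-1 L'
    lam2 <- reg_lambda^2 * mean(diag(A))
    Ainv <- MASS::ginv(A + lam2 * diag(nc))
    kernel <- t(Lw) %*% Ainv
  } else {
    w <- rep(1, nv)
    for (iter in seq_len(max_iter)) {
      Lw <- sweep(L, 2, w, "/")
      A <- tcrossprod(Lw, L)
      lam2 <- reg_lambda^2 * mean(diag(A))
      M <- MASS::ginv(A + lam2 * H)
      wn <- sqrt(pmax(colSums(L * (M %*% L)), 0))
      wn <- wn / mean(wn)
      delta <- max(abs(wn - w) / pmax(wn, 1e-300))
      w <- wn
      if (delta < fp_tol) break
    }
    if (delta >= fp_tol)
      stopf("eLORETA fixed point did not converge in %d iterations (last delta %.3g)",
            max_iter, delta)
    Lw <- sweep(L, 2, w, "/")                    # W^-1 = diag(1/w)
    A <- tcrossprod(Lw, L)
    lam2 <- reg_lambda^2 * mean(diag(A))
    M <- MASS::ginv(A + lam2 * H)
    kernel <- t(Lw) %*% M
  }
  structure(list(kernel = kernel, method = method, reg_lambda = reg_lambda,
                 weights = w, channel_names = fwd$channel_names,
                 space = fwd$space),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %s, %d vertices x %d channels, lambda=%g\n",
              x$method, nrow(x$kernel), ncol(x$kernel), x$reg_lambda))
  invisible(x)
}

#' Apply an inverse operator to sensor data
#'
#' Linear application per time/phase point. Accepts a channels x times
#' matrix, a `warped_epochs` set (returns vertices x G x n_epochs), or a
#' list of channels x times matrices.
#'
#' @param inv an `inverse_operator`.
#' @param x sensor data with channel order matching the forward model.
#' @param vertices optional vertex index subset; the estimate of each
#'   vertex is independent of the others, so restricting rows gives
#'   exactly the full solution's values at those vertices.
#' @return source amplitudes with the channel dimension replaced by
#'   vertices.
#' @export
apply_inverse <- function(inv, x, vertices = NULL) {
  if (!is.null(vertices)) {
    inv$kernel <- inv$kernel[vertices, , drop = FALSE]
  }
  check_chans <- function(nms) {
    if (!identical(as.character(nms), as.character(inv$channel_names)))
      stopf("channel order does not match the inverse operator")
  }
  if (inherits(x, "warped_epochs")) {
    d <- dim(x$epochs)
    check_chans(dimnames(x$epochs)[[1]])
    flat <- matrix(x$epochs, d[1], d[2] * d[3])
    array(inv$kernel %*% flat, c(nrow(inv$kernel), d[2], d[3]))
  } else if (is.list(x)) {
    # one concatenated multiply, split back afterwards
    if (!is.null(rownames(x[[1]]))) check_chans(rownames(x[[1]]))
    lens <- vapply(x, ncol, 0L)
    big <- inv$kernel %*% do.call(cbind, x)
    ends <- cumsum(lens)
    starts <- c(1, utils::head(ends, -1) + 1)
    lapply(seq_along(x), function(i) big[, starts[i]:ends[i], drop = FALSE])
  } else {
    if (!is.null(rownames(x))) check_chans(rownames(x))
    else if (nrow(x) != ncol(inv$kernel))
      stopf("data has %d channels, inverse expects %d", nrow(x),
            ncol(inv$kernel))
    inv$kernel %*% x
  }
}

#' Baseline-normalized z-score source maps per gait quartile
#'
#' For each vertex and quartile, the across-epoch mean of the
#' quartile-mean source amplitude is compared with the across-epoch
#' distribution of the 1-s pre-stride baseline amplitude:
#' `z = (m_active - m_base) / (s_base / sqrt(n))` (convention `"sem"`,
#' default -- evidence grows with the epoch count) or
#' `z = (m_active - m_base) / s_base` (convention `"sd"`). Amplitudes
#' enter as absolute values by default (`summary = "abs"`), since the maps
#' report activation strength for orientation-signed dipole estimates.
#'
#' @param src_epochs vertices x G x n_epochs array of source amplitudes
#'   for the warped gait cycles (from [apply_inverse()]).
#' @param baseline_src vertices x S x n_epochs array of source amplitudes
#'   for the 1-s pre-stride baselines, or a vertices x n_epochs matrix of
#'   per-epoch baseline mean amplitudes (from [baseline_source_means()],
#'   which avoids materializing the full baseline source array).
#' @param phase phase vector of the warped grid (percent); default assumes
#'   the standard grid.
#' @param convention `"sem"` or `"sd"`.
#' @param summary `"abs"` or `"signed"`.
#' @param space optional `source_space` carried through for ROI summaries.
#' @return object of class `source_map`: `z` (vertices x 4), `n_epochs`,
#'   `convention`, plus the per-quartile and baseline epoch summaries.
#' @export
zscore_maps <- function(src_epochs, baseline_src,
                        phase = 100 * (seq_len(dim(src_epochs)[2]) - 1) /
                          dim(src_epochs)[2],
                        convention = c("sem", "sd"),
                        summary = c("abs", "signed"), space = NULL) {
  convention <- match.arg(convention)
  summary <- match.arg(summary)
  dv <- dim(src_epochs)
  n <- dv[3]
  if (n < 2) stopf("need >= 2 epochs, got %d", n)
  nb <- dim(baseline_src)[length(dim(baseline_src))]
  if (nb != n)
    stopf("baseline epoch count (%d) != active epoch count (%d)", nb, n)
  f <- if (summary == "abs") abs else identity
  sl <- quartile_slices(list(phase = phase))
  # mean over the grid dimension via colMeans on a (grid, vertex*epoch) view
  mean_over_grid <- function(arr) {
    d <- dim(arr)
    matrix(colMeans(matrix(aperm(arr, c(2, 1, 3)), d[2])), d[1], d[3])
  }
  qmeans <- vapply(sl, function(idx)
    mean_over_grid(f(src_epochs[, idx, , drop = FALSE])),
    matrix(0, dv[1], n))                        # vertices x n x 4
  bmean <- if (length(dim(baseline_src)) == 2) baseline_src
           else mean_over_grid(f(baseline_src)) # vertices x n
  m_base <- rowMeans(bmean)
  s_base <- sqrt(pmax(rowMeans(bmean^2) - rowMeans(bmean)^2, 0) * n / (n - 1))
  if (any(s_base == 0))
    stopf("zero baseline sd at vertex %d", which(s_base == 0)[1])
  m_active <- apply(qmeans, c(1, 3), mean)       # vertices x 4
  denom <- if (convention == "sem") s_base / sqrt(n) else s_base
  z <- (m_active - m_base) / denom
  colnames(z) <- names(sl)
  structure(list(z = z, n_epochs = n, convention = convention,
                 summary = summary, space = space,
                 quartile_epoch_means = qmeans, baseline_epoch_means = bmean),
            class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %d vertices x %d quartiles (z, %s convention, n=%d)\n",
              nrow(x$z), ncol(x$z), x$convention, x$n_epochs))
  invisible(x)
}

#' Per-epoch baseline mean source amplitudes, computed incrementally
#'
#' Applies the inverse operator to each baseline segment in turn and keeps
#' only its per-vertex mean amplitude, so the full vertices x samples x
#' epochs baseline source array is never materialized (it can run to
#' gigabytes at 512 Hz with hundreds of strides).
#'
#' @param inv an `inverse_operator`.
#' @param baselines list of channels x samples baseline matrices (the
#'   `$baseline` field of a `gait_epochs` set).
#' @param vertices optional vertex subset.
#' @param summary `"abs"` (mean absolute amplitude, default) or
#'   `"signed"`; must match the `summary` used in [zscore_maps()].
#' @return vertices x n_epochs matrix, ready for [zscore_maps()].
#' @export
baseline_source_means <- function(inv, baselines, vertices = NULL,
                                  summary = c("abs", "signed")) {
  summary <- match.arg(summary)
  f <- if (summary == "abs") abs else identity
  K <- if (is.null(vertices)) inv$kernel else
    inv$kernel[vertices, , drop = FALSE]
  vapply(baselines, function(m) rowMeans(f(K %*% m)), numeric(nrow(K)))
}

#' Paired t-maps between two source-map stacks
#'
#' Classical paired t-statistic per vertex and quartile across subjects,
#' e.g. active vs reference condition maps.
#'
#' @param maps_A,maps_B subjects x vertices x quartiles arrays (or lists
#'   of `source_map` objects from the same subjects in the same order).
#' @return vertices x quartiles matrix of t-values.
#' @export
paired_t_maps <- function(maps_A, maps_B) {
  as_stack <- function(m) {
    if (is.list(m)) {
      arr <- simplify2array(lapply(m, function(s) s$z)) # v x q x subj
      aperm(arr, c(3, 1, 2))
    } else m
  }
  A <- as_stack(maps_A); B <- as_stack(maps_B)
  if (!all(dim(A) == dim(B))) stopf("map stacks differ in shape")
  n <- dim(A)[1]
  if (n < 2) stopf("need >= 2 subjects, got %d", n)
  D <- A - B
  m <- apply(D, c(2, 3), mean)
  s <- apply(D, c(2, 3), stats::sd)
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  t
}

#' ROI time course at the maximum-amplitude vertex
#'
#' For each region of the source space, selects the vertex whose peak
#' absolute amplitude across the phase grid is largest (ties broken by the
#' lowest vertex index) and returns its full time course.
#'
#' @param src_mean vertices x G matrix (epoch-averaged source amplitudes).
#' @param space the `source_space` the rows index.
#' @param regions regions to include; default all.
#' @return object of class `roi_timecourse`: `values` (ROI x G),
#'   `vertex_chosen` (named integer).
#' @export
roi_timecourse <- function(src_mean, space, regions = NULL) {
  stopifnot(nrow(src_mean) == n_vertices(space))
  regions <- regions %||% sort(unique(space$region))
  vals <- NULL; chosen <- integer(0)
  for (r in regions) {
    idx <- which(space$region == r)
    if (!length(idx)) stopf("empty ROI: %s", r)
    peak <- apply(abs(src_mean[idx, , drop = FALSE]), 1, max)
    v <- idx[which.max(peak)]
    vals <- rbind(vals, src_mean[v, ])
    chosen[r] <- v
  }
  rownames(vals) <- regions
  structure(list(values = vals, vertex_chosen = chosen),
            class = "roi_timecourse")
}
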