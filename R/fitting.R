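#' Structural similarity index between two matrices
#'
#' Windowed SSIM in the standard local-statistics formulation: local means,
#' variances and covariance are computed under a Gaussian window (sigma =
#' 1.5, 11 x 11 by default) over the valid interior, combined with the usual
#' stability constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, and averaged.
#' The data range `L` defaults to the joint span of both matrices, which
#' pins the constants for correlation-valued input. For matrices smaller
#' than the window the window shrinks to the largest odd size that fits.
#' `ssim(A, A)` is exactly 1 and the metric is symmetric in its arguments.
#'
#' @param A,B Numeric matrices of identical dimensions.
#' @param data_range Dynamic range `L`; default `max(A, B) - min(A, B)`.
#' @param win_size Odd window size. Default 11 (shrunk if needed).
#' @param sigma Gaussian window standard deviation. Default 1.5.
#' @return SSIM value (1 for identical matrices).
#' @export
ssim <- function(A, B, data_range = NULL, win_size = 11, sigma = 1.5) {
  if (!all(dim(A) == dim(B))) stop("matrices must have identical dimensions")
  A <- unclass(A); B <- unclass(B)
  attributes(A) <- attributes(A)["dim"]; attributes(B) <- attributes(B)["dim"]
  if (is.null(data_range)) data_range <- max(A, B) - min(A, B)
  if (data_range == 0) return(1)   # identical constant matrices
  win <- min(win_size, min(dim(A)))
  if (win %% 2 == 0) win <- win - 1
  if (win < 3) stop("matrices too small for a local-window SSIM")
  r <- (win - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  smooth <- function(X) conv2_valid_sep(X, g)
  mu1 <- smooth(A); mu2 <- smooth(B)
  s11 <- smooth(A * A) - mu1^2
  s22 <- smooth(B * B) - mu2^2
  s12 <- smooth(A * B) - mu1 * mu2
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(map)
}

# separable 'valid' 2-d convolution with a 1-d kernel g applied to rows and
# columns
conv2_valid_sep <- function(X, g) {
  win <- length(g)
  n <- nrow(X); m <- ncol(X)
  out1 <- matrix(0, n - win + 1, m)
  for (k in seq_len(win)) out1 <- out1 + g[k] * X[k:(n - win + k), , drop = FALSE]
  out2 <- matrix(0, nrow(out1), m - win + 1)
  for (k in seq_len(win)) out2 <- out2 + g[k] * out1[, k:(m - win + k), drop = FALSE]
  out2
}

#' Spectral goodness of fit (Clarkson distance)
#'
#' `lambda(x, y) = 0.5 * || x/||x|| - y/||y|| ||` (Euclidean norms); the
#' goodness of fit is `1 - lambda`, which is 1 for proportional vectors, 0
#' for anti-proportional ones, and invariant to positive rescaling of
#' either argument.
#'
#' @param x,y Numeric vectors of equal length (e.g. relative band powers).
#' @return Goodness in `[0, 1]`.
#' @export
clarkson_goodness <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("Clarkson distance undefined for a zero vector")
  1 - 0.5 * sqrt(sum((x / nx - y / ny)^2))
}

#' Cohen's d effect size
#'
#' Two-sample standardized mean difference with pooled standard deviation,
#' with the conventional qualitative bins: very small (<0.2), small
#' (0.2-0.5), moderate (0.5-0.8), large (0.8-1.2), very large (1.2-2) and
#' huge (>2).
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return List with `d` and `bin`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  d <- (mean(x) - mean(y)) / sp
  cuts <- c(0.2, 0.5, 0.8, 1.2, 2)
  labs <- c("very small", "small", "moderate", "large", "very large", "huge")
  list(d = d, bin = labs[findInterval(abs(d), cuts) + 1])
}

#' Exhaustive grid sweep of goodness of fit
#'
#' Simulates the model at every combination of two parameter-axis values,
#' repeats over seeds, computes the requested observables and their
#' goodness of fit against the supplied targets. Supported axes: `K`,
#' `rho`, `r_alpha`. Supported targets (any subset):
#' \describe{
#'   \item{spectral}{numeric vector of relative band powers (default bands
#'     theta, alpha, beta) of the region-mean EEG; metric is
#'     [clarkson_goodness()], averaged across seeds.}
#'   \item{fc_bold}{BOLD FC matrix; FCs are averaged across seeds first,
#'     then compared with [ssim()].}
#'   \item{fc_eeg}{named list of envelope-FC matrices per band; SSIM is
#'     computed per seed and band, then averaged.}
#' }
#' Cells whose simulation diverges are recorded as `NA` rather than
#' aborting the sweep. Seeds are derived deterministically from
#' `protocol$seed`.
#'
#' @param connectome [connectome()] or square matrix.
#' @param axes Named list of two numeric vectors, e.g.
#'   `list(K = ..., rho = ...)`.
#' @param params Base [jr_params()].
#' @param protocol [jr_protocol()]; `n_seeds` realisations per cell.
#' @param targets Named list of targets (see above).
#' @param spectral_bands Bands for the spectral target. Default
#'   theta/alpha/beta.
#' @param tr BOLD repetition time (s).
#' @param bold_discard Seconds of BOLD discarded as hemodynamic transient.
#' @return Named list of `fit_surface` objects, one per supplied target.
#' @export
grid_sweep <- function(connectome, axes, params = jr_params(),
                       protocol = jr_protocol(), targets,
                       spectral_bands = eeg_bands(c("theta", "alpha", "beta")),
                       tr = 2.08, bold_discard = 20) {
  stopifnot(length(axes) == 2, !is.null(names(axes)))
  known <- c("K", "rho", "r_alpha")
  if (!all(names(axes) %in% known))
    stop("axes must be among: ", paste(known, collapse = ", "))
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  n1 <- length(axes[[1]]); n2 <- length(axes[[2]])
  n_seeds <- protocol$n_seeds
  vals <- lapply(targets, function(t) matrix(NA_real_, n1, n2))
  cell <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    cell <- cell + 1L
    pars <- set_axis(params, names(axes)[1], axes[[1]][i])
    pars <- set_axis(pars, names(axes)[2], axes[[2]][j])
    acc <- list(spectral = c(), fc_bold = NULL, fc_eeg = c())
    ok <- 0L
    for (s in seq_len(n_seeds)) {
      prot <- protocol
      prot$seed <- protocol$seed + (cell - 1L) * n_seeds + (s - 1L)
      sim <- tryCatch(simulate_jr(connectome, pars, prot),
                      error = function(e) NULL)
      if (is.null(sim)) next
      ok <- ok + 1L
      if (!is.null(targets$spectral)) {
        psd <- welch_psd(rowMeans(sim$eeg), sim$fs)
        rp <- relative_band_power(psd, spectral_bands)
        acc$spectral <- c(acc$spectral,
                          clarkson_goodness(rp, targets$spectral))
      }
      if (!is.null(targets$fc_bold)) {
        bb <- simulate_bold(sim$rate_pyr, sim$fs, tr = tr,
                            t_discard = bold_discard)
        fc <- bold_fc(bb$bold, tr)
        acc$fc_bold <- if (is.null(acc$fc_bold)) unclass(fc)
                       else acc$fc_bold + unclass(fc)
      }
      if (!is.null(targets$fc_eeg)) {
        per_band <- vapply(names(targets$fc_eeg), function(bn) {
          fc <- envelope_fc(sim$eeg, sim$fs, eeg_bands(bn))
          ssim(fc, targets$fc_eeg[[bn]])
        }, numeric(1))
        acc$fc_eeg <- c(acc$fc_eeg, mean(per_band))
      }
    }
    if (ok > 0) {
      if (!is.null(targets$spectral)) vals$spectral[i, j] <- mean(acc$spectral)
      if (!is.null(targets$fc_bold))
        vals$fc_bold[i, j] <- ssim(acc$fc_bold / ok, targets$fc_bold)
      if (!is.null(targets$fc_eeg)) vals$fc_eeg[i, j] <- mean(acc$fc_eeg)
    }
  }
  out <- lapply(names(targets), function(nm) {
    structure(list(axes = axes, values = vals[[nm]], metric = nm,
                   n_seeds = n_seeds), class = "fit_surface")
  })
  names(out) <- names(targets)
  out
}

set_axis <- function(params, name, value) {
  switch(name,
    K = { params$K <- value; params },
    rho = { params$plasticity$rho <- value; params },
    r_alpha = { params$r_alpha <- value; params$circuit$r_alpha <- value; params })
}

#' @export
print.fit_surface <- function(x, ...) {
  cat("fit surface (", x$metric, "): ",
      paste(names(x$axes), lengths(x$axes), sep = " x ", collapse = ", "),
      ", ", x$n_seeds, " seed(s)\n", sep = "")
  invisible(x)
}

#' Write a fit surface as long-format delimited text
#'
#' @param surface A `fit_surface`.
#' @param path Output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_fit_surface <- function(surface, path) {
  ax <- surface$axes
  df <- expand.grid(ax[[1]], ax[[2]])
  names(df) <- names(ax)
  df$metric <- surface$metric
  df$value <- as.vector(surface$values)
  df$n_seeds <- surface$n_seeds
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Masked dual-modality parameter selection
#'
#' Applies the EEG spectral goodness surface as a mask (cells with goodness
#' at or above `threshold`) and returns the cell maximising the fMRI SSIM
#' surface within the mask. Ties are broken towards the lowest value of the
#' first axis, then of the second (by convention K before rho). An empty
#' mask yields an explicit no-fit result.
#'
#' @param eeg_surface,fmri_surface `fit_surface` objects on identical axes.
#' @param threshold EEG goodness mask threshold. Default 0.85.
#' @return An object of class `dual_fit`: list with `ok`, `threshold`,
#'   `mask`, and (when `ok`) `selected` (named axis values), `indices`, and
#'   `ssim`.
#' @export
dual_fit_select <- function(eeg_surface, fmri_surface, threshold = 0.85) {
  stopifnot(identical(eeg_surface$axes, fmri_surface$axes))
  eeg <- eeg_surface$values
  fmri <- fmri_surface$values
  mask <- !is.na(eeg) & eeg >= threshold
  if (!any(mask & !is.na(fmri))) {
    return(structure(list(ok = FALSE, threshold = threshold, mask = mask),
                     class = "dual_fit"))
  }
  cand <- which(mask & !is.na(fmri), arr.ind = TRUE)
  best <- max(fmri[cand])
  hit <- cand[fmri[cand] == best, , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]   # lowest axis1, then axis2
  i <- hit[1, 1]; j <- hit[1, 2]
  sel <- c(eeg_surface$axes[[1]][i], eeg_surface$axes[[2]][j])
  names(sel) <- names(eeg_surface$axes)
  structure(list(ok = TRUE, threshold = threshold, mask = mask,
                 selected = sel, indices = c(i, j), ssim = best),
            class = "dual_fit")
}

#' @export
print.dual_fit <- function(x, ...) {
  if (!x$ok) {
    cat("dual fit: no cell passes the EEG mask (threshold ", x$threshold,
        ")\n", sep = "")
  } else {
    cat("dual fit: ", paste(names(x$selected), signif(x$selected, 4),
                            sep = " = ", collapse = ", "),
        " (fMRI SSIM = ", signif(x$ssim, 4), ", EEG threshold ",
        x$threshold, ")\n", sep = "")
  }
  invisible(x)
}
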