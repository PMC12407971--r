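#' Structural connectome container
#'
#' Validates and wraps a structural connectivity matrix: square, symmetric
#' (within tolerance), zero diagonal, non-negative weights bounded by 1.
#'
#' @param mat Square numeric weight matrix.
#' @param labels Optional character vector of region labels.
#' @param provenance Free-text provenance note.
#' @param tol Symmetry tolerance.
#' @return An object of class `connectome`.
#' @export
connectome <- function(mat, labels = NULL, provenance = "", tol = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("connectome matrix must be square")
  if (any(!is.finite(mat))) stop("connectome matrix contains non-finite entries")
  if (max(abs(mat - t(mat))) > tol)
    stop("connectome matrix is not symmetric (max asymmetry ",
         signif(max(abs(mat - t(mat))), 3), ")")
  mat <- (mat + t(mat)) / 2
  if (any(mat < 0)) stop("connectome weights must be non-negative")
  if (max(mat) > 1 + tol)
    stop("connectome weights must lie in [0, 1]; call normalize_sc() first")
  diag(mat) <- 0
  if (!is.null(labels)) {
    if (length(labels) != nrow(mat))
      stop("labels length does not match matrix order")
    rownames(mat) <- colnames(mat) <- labels
  }
  structure(list(mat = mat, labels = labels, provenance = provenance),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("connectome:", nrow(x$mat), "regions, density",
      signif(mean(x$mat[upper.tri(x$mat)] > 0), 3),
      if (nzchar(x$provenance)) paste0("(", x$provenance, ")"), "\n")
  invisible(x)
}

#' @export
dim.connectome <- function(x) dim(x$mat)

#' Read / write a connectome as delimited text
#'
#' The on-disk format is a CSV with an optional leading `label` column;
#' reading and writing round-trip both weights and labels.
#'
#' @param path File path.
#' @param provenance Provenance note attached on read.
#' @return `load_connectome` returns a [connectome()];
#'   `save_connectome` returns `path` invisibly.
#' @export
load_connectome <- function(path, provenance = path) {
  df <- read.csv(path, check.names = FALSE)
  labels <- NULL
  if (names(df)[1] == "label") {
    labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric entries in connectome file")
  dimnames(mat) <- NULL
  connectome(mat, labels = labels, provenance = provenance)
}

#' @rdname load_connectome
#' @param conn [connectome()] to write.
#' @export
save_connectome <- function(conn, path) {
  df <- as.data.frame(conn$mat)
  names(df) <- if (is.null(conn$labels)) paste0("V", seq_len(ncol(conn$mat)))
               else conn$labels
  if (!is.null(conn$labels)) df <- cbind(label = conn$labels, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Normalise structural weights to the unit interval
#'
#' Divides all weights by the global maximum; a zero matrix passes through
#' unchanged and the operation is idempotent.
#'
#' @param conn [connectome()] or raw non-negative matrix.
#' @return [connectome()] with `max(weight) <= 1`.
#' @export
normalize_sc <- function(conn) {
  raw <- if (inherits(conn, "connectome")) conn$mat else as.matrix(conn)
  if (any(raw < 0)) stop("negative weights cannot be normalised")
  m <- max(raw)
  if (m > 0) raw <- raw / m
  connectome(raw,
             labels = if (inherits(conn, "connectome")) conn$labels else NULL,
             provenance = if (inherits(conn, "connectome")) conn$provenance else "")
}

#' Add homotopic (inter-hemispheric) connections
#'
#' DTI tractography underestimates homotopic connections; this sets the
#' anti-diagonal entries `(i, N+1-i)` -- which pair homologous regions under
#' the mirrored hemisphere ordering -- to at least `weight`, symmetrically.
#' Idempotent; the diagonal is untouched.
#'
#' @param conn [connectome()] of even order.
#' @param weight Homotopic weight; default the matrix maximum (1 for a
#'   normalised connectome).
#' @return Augmented [connectome()].
#' @export
add_homotopic <- function(conn, weight = NULL) {
  stopifnot(inherits(conn, "connectome"))
  n <- nrow(conn$mat)
  if (n %% 2 != 0) stop("homotopic augmentation needs an even matrix order")
  if (is.null(weight)) weight <- max(conn$mat)
  mat <- conn$mat
  for (i in seq_len(n)) {
    j <- n + 1 - i
    if (i != j) mat[i, j] <- mat[j, i] <- max(mat[i, j], weight)
  }
  connectome(mat, labels = conn$labels,
             provenance = paste0(conn$provenance, " +homotopic"))
}

#' Subset a connectome by region labels
#'
#' @param conn [connectome()] with labels.
#' @param keep Character vector of labels to keep (order preserved as in
#'   the connectome) or a [region_selection()].
#' @return Sub-connectome.
#' @export
select_regions <- function(conn, keep) {
  stopifnot(inherits(conn, "connectome"))
  if (inherits(keep, "region_selection")) keep <- keep$labels
  if (is.null(conn$labels)) stop("connectome has no region labels")
  missing <- setdiff(keep, conn$labels)
  if (length(missing))
    stop("unknown label(s): ", paste(missing, collapse = ", "))
  idx <- which(conn$labels %in% keep)
  connectome(conn$mat[idx, idx, drop = FALSE], labels = conn$labels[idx],
             provenance = conn$provenance)
}

#' AAL90 region table
#'
#' The 90-region AAL parcellation in the mirrored hemisphere ordering used
#' throughout the package: regions 1-45 are the left-hemisphere areas in
#' atlas order and regions 90-46 their right homologs, so that homologous
#' pairs sit on the matrix anti-diagonal.
#'
#' @return data.frame with columns `index`, `name`, `abbr`, `hemi` and
#'   `label` (abbreviation suffixed with `.L`/`.R`).
#' @export
aal90_regions <- function() {
  base <- read.csv(system.file("extdata", "aal90_regions.csv",
                               package = "mfjr"),
                   stringsAsFactors = FALSE)
  left <- data.frame(name = base$name, abbr = base$abbr, hemi = "L",
                     stringsAsFactors = FALSE)
  right <- left[rev(seq_len(nrow(left))), ]
  right$hemi <- "R"
  out <- rbind(left, right)
  out$index <- seq_len(nrow(out))
  out$label <- paste0(out$abbr, ".", out$hemi)
  out[, c("index", "name", "abbr", "hemi", "label")]
}

#' Default region selections for EEG and fMRI modelling
#'
#' The EEG selection keeps 82 areas: all cortical regions plus hippocampus
#' and amygdala, excluding the deep subcortical structures (caudate,
#' putamen, pallidum, thalamus) bilaterally. The fMRI selection keeps all
#' 90 areas.
#'
#' @param modality `"eeg"` or `"fmri"`.
#' @return An object of class `region_selection` with fields `labels` and
#'   `modality`.
#' @export
region_selection <- function(modality = c("eeg", "fmri")) {
  modality <- match.arg(modality)
  regions <- aal90_regions()
  excluded <- c("CAU", "PUT", "PAL", "THA")
  labels <- if (modality == "eeg")
    regions$label[!regions$abbr %in% excluded] else regions$label
  structure(list(labels = labels, modality = modality),
            class = "region_selection")
}

#' Synthetic modular, hemispherically mirrored connectome
#'
#' Generates a deterministic (per seed) symmetric weight matrix with
#' `n_modules` modules per hemisphere, mirrored across hemispheres so that
#' homologs pair on the anti-diagonal and [add_homotopic()] applies.
#' Within-module edges appear with probability `intra_density`, between
#' modules with `inter_density`; weights are uniform in (0, 1] and
#' inter-hemispheric edges (other than homotopic ones, which are left to
#' [add_homotopic()]) are sparse and weak.
#'
#' @param n Even number of regions (>= 2).
#' @param n_modules Modules per hemisphere. Default 2.
#' @param intra_density Within-module edge probability. Default 0.8.
#' @param inter_density Between-module edge probability. Default 0.2.
#' @param seed RNG seed.
#' @return A normalised [connectome()] with synthetic labels `L1..`, `R1..`.
#' @export
synthetic_connectome <- function(n, n_modules = 2, intra_density = 0.8,
                                 inter_density = 0.2, seed = 1) {
  stopifnot(n >= 2, n %% 2 == 0,
            intra_density >= 0, intra_density <= 1,
            inter_density >= 0, inter_density <= 1)
  h <- n / 2
  module <- rep(seq_len(n_modules), length.out = h)
  mat <- withr::with_seed(seed, {
    W <- matrix(0, h, h)
    for (i in seq_len(h)) for (j in seq_len(h)) {
      if (j <= i) next
      dens <- if (module[i] == module[j]) intra_density else inter_density
      if (runif(1) < dens) W[i, j] <- W[j, i] <- runif(1)
    }
    full <- matrix(0, n, n)
    full[seq_len(h), seq_len(h)] <- W
    # mirror: region i pairs with n + 1 - i
    full[(h + 1):n, (h + 1):n] <- W[rev(seq_len(h)), rev(seq_len(h))]
    # weak sparse cross-hemisphere background
    for (i in seq_len(h)) for (j in (h + 1):n) {
      if (i == n + 1 - j) next
      if (runif(1) < inter_density / 2) {
        w <- runif(1, 0, 0.3)
        full[i, j] <- full[j, i] <- w
      }
    }
    full
  })
  labels <- c(paste0("L", seq_len(h)), paste0("R", rev(seq_len(h))))
  normalize_sc(connectome(pmin(mat, 1), labels = labels,
                          provenance = sprintf("synthetic(seed=%d)", seed)))
}
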