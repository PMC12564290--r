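#' Functional connectivity from ROI time series
#'
#' Pearson correlation between every pair of ROI columns. The diagonal is
#' forced to 1 and any ROI with zero temporal variance gets correlation 0 with
#' every other ROI (keeping feature dimensionality fixed across subjects
#' rather than producing NaN or dropping the region). No Fisher z-transform is
#' applied: the raw correlation is the feature.
#'
#' @param ts T x M numeric matrix, one row per timepoint, one column per ROI;
#'   T >= 3 and M >= 2.
#' @return A `popconn_view` list with elements `S` (M x M symmetric
#'   correlation matrix), `U` (strict upper triangle of `S` in row-major
#'   order, length M(M-1)/2), `subject`, `atlas`.
#' @export
#' @examples
#' ts <- matrix(rnorm(60), 20, 3)
#' v <- pearson_fc(ts)
#' range(v$S)
pearson_fc <- function(ts) {
  ts <- check_matrix(ts, "ts")
  if (nrow(ts) < 3) abort("need at least 3 timepoints for Pearson correlation")
  if (ncol(ts) < 2) abort("need at least 2 ROIs")
  sds <- apply(ts, 2, stats::sd)
  degenerate <- which(sds == 0)
  S <- suppressWarnings(stats::cor(ts))
  if (length(degenerate)) {
    S[degenerate, ] <- 0
    S[, degenerate] <- 0
  }
  S[!is.finite(S)] <- 0
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(
    list(S = S, U = upper_tri_vector(S),
         subject = attr(ts, "subject"), atlas = attr(ts, "atlas")),
    class = "popconn_view"
  )
}

#' Strict upper triangle of a symmetric matrix, row-major
#'
#' Fixed ordering (1,2), (1,3), ..., (1,M), (2,3), ..., (M-1,M). The same
#' ordering is used by the region-masking operators so matrix and vector
#' masks address identical entries.
#'
#' @param S Square numeric matrix.
#' @return Numeric vector of length M(M-1)/2.
#' @export
upper_tri_vector <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) abort("`S` must be a square matrix")
  t(S)[lower.tri(S)]
}

#' Rebuild a symmetric matrix from its row-major strict upper triangle
#'
#' Inverse of [upper_tri_vector()] with a unit diagonal.
#'
#' @param u Vector of length M(M-1)/2.
#' @param M Matrix dimension.
#' @param diag_value Value for the diagonal (default 1).
#' @return M x M symmetric matrix.
#' @export
fc_from_upper_tri <- function(u, M, diag_value = 1) {
  M <- check_count(M, "M", min = 2)
  if (length(u) != M * (M - 1) / 2) {
    abort(sprintf("length(u) = %d but M(M-1)/2 = %d", length(u), M * (M - 1) / 2))
  }
  S <- matrix(0, M, M)
  S[lower.tri(S)] <- u   # column-major lower triangle == row-major upper
  S <- t(S)
  S <- S + t(S)
  diag(S) <- diag_value
  S
}

# Row-major index of pair (i, j), i < j, within the upper-tri vector.
pair_index <- function(i, j, M) {
  a <- pmin(i, j); b <- pmax(i, j)
  (a - 1) * M - a * (a - 1) / 2 + (b - a)
}

#' Build per-atlas connectivity views for a cohort
#'
#' For each atlas, computes [pearson_fc()] per subject (in phenotype-table
#' order) and stacks the upper-triangle features into an N x d matrix.
#'
#' @param cohort A `popconn_cohort`, or a directory previously written by
#'   [write_cohort()].
#' @param atlases Optional character vector restricting which atlases to
#'   build; default all.
#' @return A `popconn_views` list: per atlas, `list(atlas, M, fc, X)` where
#'   `fc` is the list of S matrices and `X` the N x M(M-1)/2 feature matrix;
#'   plus the phenotype tibble as attribute-like element `phenotypes`.
#' @export
build_views <- function(cohort, atlases = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(cohort, "popconn_cohort")) {
    abort("`cohort` must be a popconn_cohort or a cohort directory")
  }
  atlases <- atlases %||% names(cohort$series)
  missing_atlas <- setdiff(atlases, names(cohort$series))
  if (length(missing_atlas)) {
    abort(sprintf("no time series for atlas %s", missing_atlas[1]))
  }
  ph <- cohort$phenotypes
  views <- lapply(atlases, function(atlas) {
    mats <- cohort$series[[atlas]]
    if (length(mats) != nrow(ph)) {
      abort(sprintf("missing series for subject %s under atlas %s",
                    ph$SUB_ID[length(mats) + 1], atlas))
    }
    fc <- lapply(seq_len(nrow(ph)), function(i) {
      v <- pearson_fc(mats[[i]])
      v$S
    })
    X <- do.call(rbind, lapply(fc, upper_tri_vector))
    rownames(X) <- as.character(ph$SUB_ID)
    list(atlas = atlas, M = ncol(fc[[1]]), fc = fc, X = X)
  })
  names(views) <- atlases
  structure(list(views = views, phenotypes = ph), class = "popconn_views")
}

#' @export
print.popconn_views <- function(x, ...) {
  cat(sprintf("<popconn_views> %d subjects x %d atlas view(s): %s\n",
              nrow(x$phenotypes), length(x$views),
              paste(vapply(x$views, function(v)
                sprintf("%s(M=%d,d=%d)", v$atlas, v$M, ncol(v$X)),
                character(1)), collapse = ", ")))
  invisible(x)
}
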