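#' Longitudinal functional dataset
#'
#' Bundles scalar responses, longitudinal observation times, subject
#' identifiers and a functional covariate observed on a common dense grid
#' (one row per observation, one column per grid point). Rows are reordered
#' so that observations from the same subject are contiguous, subjects kept
#' in order of first appearance.
#'
#' @param subject_id Vector (any atomic type) of subject identifiers, one
#'   per observation.
#' @param t Numeric vector of longitudinal times (e.g. lactation day).
#' @param y Numeric vector of responses.
#' @param curves Numeric matrix, observations x H, the functional covariate
#'   evaluated at `grid`.
#' @param grid Strictly increasing numeric vector of length H (e.g. hour of
#'   day).
#' @return An object of class `"fq_data"` with fields `subject_id`, `subject`
#'   (integer index 1..N), `t`, `y`, `curves`, `grid`, `N`, `M`, `n_i`.
#' @export
fq_dataset <- function(subject_id, t, y, curves, grid) {
  curves <- as.matrix(curves)
  M <- length(y)
  if (length(subject_id) != M || length(t) != M || nrow(curves) != M)
    stop("subject_id, t, y and curves must describe the same observations")
  if (ncol(curves) != length(grid))
    stop("curves must have one column per grid point")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (anyNA(y) || any(!is.finite(y))) stop("y contains missing or non-finite values")
  if (anyNA(t) || anyNA(curves)) stop("t and curves must be complete")
  subj <- match(subject_id, unique(subject_id))
  ord <- order(subj, seq_along(subj))   # stable: group by subject
  subj <- subj[ord]
  structure(list(subject_id = subject_id[ord], subject = subj,
                 t = as.numeric(t)[ord], y = as.numeric(y)[ord],
                 curves = curves[ord, , drop = FALSE],
                 grid = as.numeric(grid),
                 N = max(subj), M = M, n_i = as.integer(table(subj))),
            class = "fq_data")
}

#' @export
print.fq_data <- function(x, ...) {
  cat("Longitudinal functional dataset:", x$M, "observations,",
      x$N, "subjects\n")
  cat("  repeated measures per subject:", min(x$n_i), "-", max(x$n_i), "\n")
  cat("  functional covariate on", length(x$grid), "grid points in [",
      min(x$grid), ",", max(x$grid), "]\n")
  invisible(x)
}

#' Write a dataset as the two-file CSV layout
#'
#' Responses go to a long CSV with columns `subject_id`, `t`, `y`; curves to
#' a wide CSV with columns `subject_id`, `t` followed by one numeric column
#' per grid point, headed by the grid values.
#'
#' @param data An [fq_dataset()] object.
#' @param responses_path,covariates_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_fq_dataset <- function(data, responses_path, covariates_path) {
  stopifnot(inherits(data, "fq_data"))
  # %.17g keeps doubles exact under write -> read round trips
  num <- function(x) sprintf("%.17g", x)
  resp <- data.frame(subject_id = data$subject_id, t = num(data$t),
                     y = num(data$y))
  utils::write.csv(resp, responses_path, row.names = FALSE)
  curves_chr <- matrix(num(data$curves), nrow = data$M)
  cov <- data.frame(subject_id = data$subject_id, t = num(data$t),
                    curves_chr, check.names = FALSE)
  names(cov) <- c("subject_id", "t", num(data$grid))
  utils::write.csv(cov, covariates_path, row.names = FALSE, quote = FALSE)
  invisible(c(responses_path, covariates_path))
}

#' Read a dataset from the two-file CSV layout
#'
#' Validates that the `(subject_id, t)` keys of the two files match
#' one-to-one and that the covariate header is a strictly increasing numeric
#' grid; errors name the offending keys or rows.
#'
#' @param responses_path CSV with columns `subject_id`, `t`, `y`.
#' @param covariates_path CSV with columns `subject_id`, `t`, then H numeric
#'   columns headed by the grid values.
#' @return An [fq_dataset()] object.
#' @export
read_fq_dataset <- function(responses_path, covariates_path) {
  resp <- utils::read.csv(responses_path, check.names = FALSE)
  need <- c("subject_id", "t", "y")
  if (!all(need %in% names(resp)))
    stop("responses file must have columns subject_id, t, y")
  if (anyNA(resp$y))
    stop("NA responses at rows: ",
         paste(which(is.na(resp$y)), collapse = ", "))
  cov <- utils::read.csv(covariates_path, check.names = FALSE)
  if (!all(c("subject_id", "t") %in% names(cov)[1:2]))
    stop("covariates file must start with columns subject_id, t")
  grid <- suppressWarnings(as.numeric(names(cov)[-(1:2)]))
  if (anyNA(grid)) stop("covariate columns must be headed by numeric grid values")
  if (any(diff(grid) <= 0)) stop("grid header must be strictly increasing")
  key_r <- paste(resp$subject_id, resp$t, sep = "\r")
  key_c <- paste(cov$subject_id, cov$t, sep = "\r")
  if (anyDuplicated(key_r))
    stop("duplicate (subject_id, t) keys in responses: ",
         paste(unique(key_r[duplicated(key_r)]), collapse = "; "))
  if (anyDuplicated(key_c))
    stop("duplicate (subject_id, t) keys in covariates: ",
         paste(unique(key_c[duplicated(key_c)]), collapse = "; "))
  miss_in_cov <- setdiff(key_r, key_c)
  miss_in_resp <- setdiff(key_c, key_r)
  if (length(miss_in_cov))
    stop("response rows without matching covariate row: ",
         paste(gsub("\r", "/", miss_in_cov), collapse = "; "))
  if (length(miss_in_resp))
    stop("covariate rows without matching response row: ",
         paste(gsub("\r", "/", miss_in_resp), collapse = "; "))
  idx <- match(key_r, key_c)
  fq_dataset(resp$subject_id, resp$t, resp$y,
             as.matrix(cov[idx, -(1:2), drop = FALSE]), grid)
}
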