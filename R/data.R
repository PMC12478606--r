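#' Construct a validated multi-group item response dataset
#'
#' Bundles a binary response matrix, a group membership vector, and a
#' Q-matrix of item-by-dimension loading indicators into the container used
#' by all fitting functions. Group 1 is always the reference group.
#'
#' @param Y N x J matrix of 0/1 item responses (no missing values).
#' @param group length-N integer vector of group codes in `1..G`; every code
#'   from 1 to `max(group)` must occur at least once. Group 1 is the
#'   reference group whose DIF parameters are fixed at zero.
#' @param Q J x K matrix of 0/1 loading indicators; row j gives the latent
#'   dimensions item j loads on, and every row must contain at least one 1.
#' @return An object of class `remirt_data`: a list with elements `Y`,
#'   `group`, `Q`, the dimensions `N`, `J`, `K`, `G`, and `support`, a list
#'   of per-item loading index sets.
#' @examples
#' Q <- rbind(c(1, 0), c(1, 0), c(0, 1))
#' Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
#' d <- remirt_data(Y, c(1, 1, 2, 2), Q)
#' d$support
#' @export
remirt_data <- function(Y, group, Q) {
  Y <- as.matrix(Y)
  Q <- as.matrix(Q)
  storage.mode(Y) <- "double"
  storage.mode(Q) <- "double"
  group <- as.integer(group)

  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop("missing response at row ", bad[1], ", column ", bad[2],
         ": missing data are not supported")
  }
  bad <- which(!(Y == 0 | Y == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("response matrix must contain only 0/1; found ", Y[bad[1, 1], bad[1, 2]],
         " at row ", bad[1, 1], ", column ", bad[1, 2])
  }
  if (length(group) != nrow(Y)) {
    stop("group vector has length ", length(group),
         " but the response matrix has ", nrow(Y), " rows")
  }
  if (anyNA(group) || any(group < 1)) {
    stop("group codes must be positive integers (1 = reference group)")
  }
  G <- max(group)
  missing_g <- setdiff(seq_len(G), unique(group))
  if (length(missing_g) > 0) {
    stop("group code(s) ", paste(missing_g, collapse = ", "),
         " do not occur; codes must cover 1..G")
  }
  if (nrow(Q) != ncol(Y)) {
    stop("Q-matrix has ", nrow(Q), " rows but the response matrix has ",
         ncol(Y), " columns (items)")
  }
  if (any(!(Q == 0 | Q == 1))) stop("Q-matrix must contain only 0/1")
  empty <- which(rowSums(Q) == 0)
  if (length(empty) > 0) {
    stop("Q-matrix row(s) ", paste(empty, collapse = ", "),
         " have no loading; every item must load on at least one dimension")
  }

  structure(list(
    Y = Y, group = group, Q = Q,
    N = nrow(Y), J = ncol(Y), K = ncol(Q), G = G,
    support = apply(Q > 0, 1, which, simplify = FALSE)
  ), class = "remirt_data")
}

#' @export
print.remirt_data <- function(x, ...) {
  cat("Multi-group item response data\n")
  cat("  persons:", x$N, " items:", x$J, " dimensions:", x$K,
      " groups:", x$G, "\n")
  cat("  group sizes:", paste(tabulate(x$group, x$G), collapse = ", "), "\n")
  invisible(x)
}

## read a numeric CSV, tolerating an optional header line
.read_numeric_csv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  m <- as.matrix(read.csv(path, header = has_header))
  if (anyNA(suppressWarnings(storage.mode(m) <- "double"))) {
    stop(what, " file ", path, " contains non-numeric entries")
  }
  dimnames(m) <- NULL
  m
}

#' Read responses, group membership, and Q-matrix from CSV files
#'
#' Files are row-aligned: person i is row i of both the response and the
#' group file. Headers are optional and detected automatically. Validation
#' failures report the offending cell.
#'
#' @param responses path to an N x J CSV of 0/1 responses.
#' @param groups path to an N x 1 CSV of integer group codes (1 = reference).
#' @param qmatrix path to a J x K CSV of 0/1 loading indicators.
#' @return A [remirt_data] object.
#' @export
read_remirt_data <- function(responses, groups, qmatrix) {
  Y <- .read_numeric_csv(responses, "responses")
  g <- .read_numeric_csv(groups, "groups")
  Q <- .read_numeric_csv(qmatrix, "qmatrix")
  if (ncol(g) != 1) stop("groups file must have exactly one column")
  if (nrow(g) != nrow(Y)) {
    stop("groups file has ", nrow(g), " rows but responses file has ",
         nrow(Y), " rows")
  }
  if (any(g != round(g))) stop("group codes must be integers")
  remirt_data(Y, as.integer(g[, 1]), Q)
}
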