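# Linear-programming backend.
#
# The optimizer's stage problems are sparse LPs (tens of thousands of rows).
# They are solved with HiGHS as shipped inside scipy, through a small
# bundled Python helper called as a subprocess; data travel as binary
# triplet files. HiGHS with fixed settings is deterministic, which the
# pipeline relies on for bit-reproducible plans.

.lp_python <- function() {
  getOption("protonMCO.python", Sys.getenv("PROTONMCO_PYTHON", "python"))
}

.lp_script <- function() {
  p <- system.file("python", "solve_lp.py", package = "protonMCO")
  if (!nzchar(p)) {
    # development tree fallback (package not installed)
    cand <- file.path(c("inst/python", "python"), "solve_lp.py")
    p <- cand[file.exists(cand)][1]
    if (is.na(p)) .stopf("solve_lp.py helper not found")
  }
  p
}

#' Solve a sparse linear program
#'
#' Minimizes `obj' x` subject to `A x <= b` and `lb <= x <= ub`
#' (element-wise; defaults x >= 0). Backend: HiGHS via scipy.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (dgCMatrix, dgTMatrix or dense), m x n; may
#'   have zero rows.
#' @param b numeric RHS (length m).
#' @param lb,ub variable bounds, scalar or length n (default 0, Inf).
#' @param allow_infeasible if TRUE, return status instead of erroring on an
#'   infeasible/unbounded model.
#' @return list(x, objective, status, message); status 0 = optimal.
#' @export
solveLP <- function(obj, A, b, lb = 0, ub = Inf, allow_infeasible = FALSE) {
  n <- length(obj)
  if (is.null(A)) {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0L, n))
    b <- numeric(0)
  }
  if (!inherits(A, "TsparseMatrix")) {
    A <- methods::as(methods::as(as(A, "CsparseMatrix"), "generalMatrix"),
                     "TsparseMatrix")
  }
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  lb[!is.finite(lb)] <- -1e30
  ub[ub > 1e30] <- 1e30

  d <- tempfile("lp_")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  wb <- function(name, v, int = FALSE) {
    con <- file(file.path(d, name), "wb")
    on.exit(close(con), add = TRUE)
    if (int) writeBin(as.integer(v), con, size = 4L) else writeBin(as.numeric(v), con)
  }
  writeLines(jsonlite::toJSON(
    list(n = n, m = m, nnz = length(A@x),
         method = getOption("protonMCO.lp_method", "highs-ipm")),
    auto_unbox = TRUE), file.path(d, "meta.json"))
  wb("c.bin", obj); wb("b.bin", b); wb("lb.bin", lb); wb("ub.bin", ub)
  wb("ai.bin", A@i, int = TRUE); wb("aj.bin", A@j, int = TRUE); wb("ax.bin", A@x)

  rc <- system2(.lp_python(), c(.lp_script(), d), stdout = TRUE, stderr = TRUE)
  res_file <- file.path(d, "result.json")
  if (!file.exists(res_file)) {
    .stopf("LP backend failed: %s", paste(rc, collapse = "\n"))
  }
  res <- jsonlite::fromJSON(res_file)
  x <- readBin(file.path(d, "x.bin"), "numeric", n = n)
  out <- list(x = x, objective = res$fun, status = res$status,
              message = res$message)
  if (res$status != 0 && !allow_infeasible) {
    .stopf("LP not solved to optimality (status %d): %s", res$status, res$message)
  }
  out
}
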