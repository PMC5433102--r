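## Mixed-integer linear programming backend.
##
## Models are held as a sparse triplet constraint system and handed to an
## external HiGHS solver process (scipy.optimize.milp). The exchange format
## is JSON on disk; infinities are encoded as +/-1e30.

BIGBND <- 1e30

#' Locate the Python interpreter used for the MILP backend
#'
#' The copy-number tree solver delegates the branch-and-bound search to
#' HiGHS through `scipy.optimize.milp`, run in a `python` subprocess. Set
#' `options(cnphylo.python = "/path/to/python")` to override the `python`
#' found on the `PATH`.
#'
#' @return path to the interpreter.
#' @export
milp_python <- function() {
  py <- getOption("cnphylo.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no python interpreter found for the MILP backend; ",
         "set options(cnphylo.python = ...)", call. = FALSE)
  }
  py
}

## obj: objective coefficients (minimize); lb/ub: variable bounds;
## integrality: logical per variable; ai/aj/av: constraint matrix triplets
## (1-based); rl/ru: row bounds. Returns list(status, objective, x, bound,
## gap). status: "optimal", "feasible" (limit hit, incumbent available),
## "infeasible", "unbounded" or "unknown".
milp_solve <- function(obj, lb, ub, integrality, ai, aj, av, rl, ru,
                       time_limit = 600, verbose = FALSE) {
  nvar <- length(obj)
  stopifnot(length(lb) == nvar, length(ub) == nvar,
            length(integrality) == nvar,
            length(ai) == length(aj), length(aj) == length(av),
            length(rl) == length(ru))
  clip <- function(x) pmin(pmax(x, -BIGBND), BIGBND)
  model <- list(
    ncol = nvar, nrow = length(rl),
    obj = obj, lb = clip(lb), ub = clip(ub),
    integrality = as.integer(integrality),
    ai = ai - 1L, aj = aj - 1L, av = av,
    rl = clip(rl), ru = clip(ru),
    time_limit = time_limit
  )
  mfile <- tempfile("milp_model_", fileext = ".json")
  sfile <- tempfile("milp_out_", fileext = ".json")
  on.exit(unlink(c(mfile, sfile)), add = TRUE)
  jsonlite::write_json(model, mfile, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_highs.py", package = "cnphylo")
  if (!nzchar(script)) stop("MILP backend script not found", call. = FALSE)
  out <- suppressWarnings(
    system2(milp_python(), c(shQuote(script), shQuote(mfile), shQuote(sfile)),
            stdout = TRUE, stderr = TRUE)
  )
  code <- attr(out, "status")
  if (!file.exists(sfile) || (!is.null(code) && code != 0L)) {
    stop("MILP backend failed:\n", paste(out, collapse = "\n"), call. = FALSE)
  }
  if (verbose && length(out)) message(paste(out, collapse = "\n"))
  res <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  res$x <- as.numeric(res$x)
  res
}
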