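#' @section Solver backend:
#' pathflux formulates every optimization itself (stoichiometry, bounds,
#' slack and binary-use variables, objectives) and hands the resulting
#' standard-form LP/MILP/QP to a bundled Python worker
#' (`inst/python/pfsolve.py`) that solves it with SciPy's HiGHS interface
#' (`scipy.optimize.milp`) and `trust-constr`.  A persistent worker process
#' is started lazily and reused over a localhost socket; if that fails for
#' any reason each solve falls back to a one-shot subprocess.  Set
#' `options(pathflux.python = "/path/to/python")` to pick the interpreter.
#'
#' @name pathflux-solver
#' @keywords internal
NULL

.pf <- new.env(parent = emptyenv())

pf_python <- function() {
  opt <- getOption("pathflux.python", "")
  if (nzchar(opt)) return(opt)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found; set options(pathflux.python = ...)",
       call. = FALSE)
}

pf_script <- function() {
  p <- system.file("python", "pfsolve.py", package = "pathflux")
  if (!nzchar(p)) {
    # during in-source testing without installation
    p <- file.path("inst", "python", "pfsolve.py")
  }
  normalizePath(p, mustWork = TRUE)
}

pf_worker_start <- function() {
  portfile <- tempfile("pfport")
  logfile <- tempfile("pflog")
  system2(pf_python(), c(shQuote(pf_script()), "serve", shQuote(portfile)),
          stdout = logfile, stderr = logfile, wait = FALSE)
  port <- NA_integer_
  for (i in 1:300) {  # up to 30 s for the interpreter to come up
    if (file.exists(portfile)) {
      txt <- tryCatch(readLines(portfile, warn = FALSE), error = function(e) "")
      if (length(txt) && nzchar(txt[1])) {
        port <- as.integer(txt[1])
        break
      }
    }
    Sys.sleep(0.1)
  }
  if (is.na(port)) {
    stop("pathflux solver worker failed to start; log:\n",
         paste(readLines(logfile, warn = FALSE), collapse = "\n"),
         call. = FALSE)
  }
  con <- socketConnection("127.0.0.1", port = port, blocking = TRUE,
                          open = "r+", timeout = 600)
  .pf$con <- con
  # handshake
  resp <- pf_worker_call(list(cmd = "ping"))
  stopifnot(isTRUE(resp$ok))
  invisible(con)
}

pf_worker_call <- function(req) {
  payload <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA,
                              null = "null")
  writeLines(payload, .pf$con)
  flush(.pf$con)
  line <- readLines(.pf$con, n = 1, warn = FALSE)
  if (length(line) == 0) stop("solver worker closed the connection")
  jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

pf_worker_reset <- function() {
  if (!is.null(.pf$con)) {
    try(close(.pf$con), silent = TRUE)
    .pf$con <- NULL
  }
}

pf_solve_once <- function(req) {
  fin <- tempfile("pfreq", fileext = ".json")
  fout <- tempfile("pfres", fileext = ".json")
  jsonlite::write_json(req, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(pf_python(), c(shQuote(pf_script()), "once",
                                   shQuote(fin), shQuote(fout)))
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("pathflux one-shot solver failed (exit ", status, ")",
         call. = FALSE)
  }
  jsonlite::fromJSON(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

#' Solve a standard-form problem through the backend
#'
#' Internal entry point used by all modules.  `problem` is a list with
#' `kind` (`"milp"` or `"qp"`), `nvar`, `Aeq`/`beq` (and optionally
#' `Aub`/`bub`), `lb`, `ub`, `c`, plus `integrality`, `stage2_c`, `qdiag`,
#' and optionally `variants` (a list of per-solve overrides sharing the
#' constraint matrices).
#'
#' @param problem the request list (see details).
#' @return list of result lists (`status`, `x`, `objective`, ...), one per
#'   variant (length 1 when no variants were given).
#' @keywords internal
pf_solve <- function(problem) {
  resp <- tryCatch({
    if (is.null(.pf$con)) pf_worker_start()
    pf_worker_call(problem)
  }, error = function(e) {
    pf_worker_reset()
    pf_solve_once(problem)
  })
  if (!isTRUE(resp$ok)) {
    stop(errorCondition(paste0("solver backend error: ", resp$error),
                        class = c("pf_solver_error", "error")))
  }
  resp$results
}

# dense/sparse matrix -> triplet list for the JSON protocol (0-based)
pf_triplets <- function(M) {
  M <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  list(i = M@i, j = M@j, x = M@x, m = nrow(M))
}

pf_check_status <- function(res, what = "optimization") {
  if (!identical(res$status, "optimal")) {
    stop(errorCondition(
      paste0(what, " failed: solver status '", res$status, "'"),
      class = c("pf_solver_error", "error")))
  }
  invisible(res)
}
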