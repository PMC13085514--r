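# Bridge to the bundled RDKit helper script (inst/python/chem_backend.py).
# All calls are batched: one python process per request, JSON in/out via
# temp files, results memoised per (operation, options, SMILES) so repeated
# featurization of the same structures costs nothing.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- getOption("dt50prob.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no `python` interpreter found on PATH", call. = FALSE)
  py
}

chem_backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "dt50prob")
  if (!nzchar(path)) stop("chem_backend.py not found in installed package", call. = FALSE)
  path
}

#' Is the RDKit backend available?
#'
#' Checks that a `python` interpreter with RDKit can be invoked. Used to give
#' an early, readable error; all chemistry operations require it.
#'
#' @return `TRUE` or `FALSE`.
#' @export
chem_backend_available <- function() {
  ok <- tryCatch({
    res <- chem_batch("standardize", "C")
    isTRUE(res[[1]]$ok)
  }, error = function(e) FALSE)
  isTRUE(ok)
}

# Run one batched backend request. Returns a list of per-SMILES records.
chem_batch <- function(op, smiles, options = list()) {
  stopifnot(is.character(smiles))
  opt_key <- if (length(options)) {
    paste(names(options), vapply(options, function(x) paste(x, collapse = ","),
                                 character(1)),
          sep = "=", collapse = ";")
  } else ""
  keys <- paste(op, opt_key, smiles, sep = "\r")
  out <- vector("list", length(smiles))
  hit <- vapply(keys, function(k) !is.null(.chem_cache[[k]]), logical(1))
  if (any(hit)) out[hit] <- lapply(keys[hit], function(k) .chem_cache[[k]])
  if (any(!hit)) {
    todo <- which(!hit)
    # de-duplicate identical SMILES within the request
    uniq <- unique(smiles[todo])
    # as.list keeps a length-1 batch a JSON *array* under auto_unbox
    req <- list(op = op, smiles = as.list(uniq), options = options)
    infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
    on.exit(unlink(c(infile, outfile)), add = TRUE)
    jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA, null = "null")
    status <- suppressWarnings(
      system2(chem_python(), c(chem_backend_script(), infile, outfile),
              stdout = FALSE, stderr = FALSE))
    if (!identical(status, 0L) || !file.exists(outfile)) {
      stop("chemistry backend call failed (op = ", op, ", exit status ", status, ")",
           call. = FALSE)
    }
    resp <- jsonlite::read_json(outfile)
    if (!isTRUE(resp$ok)) stop("chemistry backend error: ", resp$error, call. = FALSE)
    res_by_smiles <- stats::setNames(resp$results, uniq)
    for (i in todo) {
      rec <- res_by_smiles[[smiles[i]]]
      .chem_cache[[keys[i]]] <- rec
      out[[i]] <- rec
    }
  }
  out
}

chem_cache_clear <- function() {
  rm(list = ls(.chem_cache, all.names = TRUE), envir = .chem_cache)
  invisible(NULL)
}
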