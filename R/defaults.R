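#' Locate a shipped defaults file
#'
#' Versioned defaults (cohort calibration, planar model, patellar mechanism)
#' live in the package's \code{extdata} directory rather than in code, so
#' they can be inspected, versioned and swapped.
#'
#' @param name one of \code{"cohort"}, \code{"model"}, \code{"mechanism"}.
#' @return path to the JSON defaults file.
#' @export
default_file <- function(name = c("cohort", "model", "mechanism")) {
  name <- match.arg(name)
  fname <- switch(name,
    cohort = "cohort_defaults.json",
    model = "planar_model_defaults.json",
    mechanism = "patellar_mechanism_default.json")
  path <- system.file("extdata", fname, package = "pfjload")
  if (!nzchar(path)) stop("defaults file not found: ", fname)
  path
}

read_defaults_json <- function(path) {
  if (!file.exists(path)) stop("configuration error: file does not exist: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# internal: run expr with a locally-seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("configuration error: seed must be a single number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# internal: derive a stream of sub-seeds below 2^31 from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
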