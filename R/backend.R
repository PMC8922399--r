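#' @title RDKit chemistry backend
#' @description Internal plumbing that delegates chemistry perception to the
#'   bundled RDKit batch script (`inst/python/chem_backend.py`). Every call
#'   writes one JSON request, runs one interpreter, and parses one JSON
#'   reply, so callers batch molecules aggressively.
#' @name chem-backend
#' @keywords internal
NULL

.mtqsar_env <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for chemistry perception
#'
#' Resolution order: `options(mtqsar.python=)`, the `MTQSAR_PYTHON`
#' environment variable, then `python` / `python3` on `PATH`.
#'
#' @return Path to the interpreter.
#' @export
find_chem_python <- function() {
  opt <- getOption("mtqsar.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("MTQSAR_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python", "python3")) {
    hit <- Sys.which(cand)
    if (nzchar(hit)) return(unname(hit))
  }
  stop("No Python interpreter found; set options(mtqsar.python=) or MTQSAR_PYTHON")
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "mtqsar")
  if (!nzchar(path)) stop("chem_backend.py not found in the installed package")
  path
}

chem_call <- function(op, payload = list()) {
  payload$op <- op
  req <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, out)), add = TRUE)
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA)
  status <- system2(find_chem_python(), c(backend_script(), req, out),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(out)) {
    stop("chemistry backend failed (op = ", op, ", exit status ", status, ")")
  }
  jsonlite::read_json(out, simplifyVector = FALSE)
}

#' Standardize SMILES strings
#'
#' Applies structure normalization, largest-fragment desalting and charge
#' neutralization, returning RDKit canonical SMILES. The canonical string is
#' the unique identity of a compound throughout the package. Unparseable
#' inputs are rejected (NA) with a reason, never an error, so that raw
#' multi-source tables can be cleaned row by row.
#'
#' @param smiles Character vector of structure strings.
#' @return A data.frame with columns `input`, `canonical` (NA on rejection)
#'   and `reason` (NA on success).
#' @examples \dontrun{chem_standardize(c("CCO", "CCN.Cl"))}
#' @export
chem_standardize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(data.frame(input = character(), canonical = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  res <- chem_call("standardize", list(smiles = smiles))
  data.frame(
    input = smiles,
    canonical = vapply(res, function(r) if (isTRUE(r$ok)) r$canonical else NA_character_, ""),
    reason = vapply(res, function(r) if (isTRUE(r$ok)) NA_character_ else r$reason, ""),
    stringsAsFactors = FALSE
  )
}

#' Raw atom/bond perception for a batch of molecules (internal).
#' @return List per molecule: n_atoms, atoms (list of records), bonds.
#' @keywords internal
chem_perceive <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  res <- chem_call("featurize", list(smiles = smiles))
  bad <- which(!vapply(res, function(r) isTRUE(r$ok), TRUE))
  if (length(bad)) {
    stop("unparseable structure at position ", bad[1], ": ", smiles[bad[1]])
  }
  res
}

#' Binary fingerprints for a batch of molecules
#'
#' @param smiles Character vector.
#' @param kind `"morgan"` (circular/ECFP-style) or `"maccs"` (167 structural
#'   keys).
#' @param radius Morgan radius (2 corresponds to ECFP4).
#' @param nbits Folded length for Morgan fingerprints.
#' @return 0/1 integer matrix, one row per molecule.
#' @export
chem_fingerprints <- function(smiles, kind = c("morgan", "maccs"),
                              radius = 2L, nbits = 2048L) {
  kind <- match.arg(kind)
  stopifnot(is.character(smiles), length(smiles) >= 1)
  res <- chem_call("fingerprints",
                   list(smiles = smiles, kind = kind,
                        radius = as.integer(radius), nbits = as.integer(nbits)))
  bad <- which(!vapply(res, function(r) isTRUE(r$ok), TRUE))
  if (length(bad)) stop("unparseable structure: ", smiles[bad[1]])
  width <- res[[1]]$nbits
  m <- matrix(0L, nrow = length(smiles), ncol = width)
  for (i in seq_along(res)) {
    on <- unlist(res[[i]]$onbits)
    if (length(on)) m[i, on] <- 1L
  }
  rownames(m) <- smiles
  m
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Bickerton's composite desirability in `[0, 1]`; higher means more
#' drug-like.
#'
#' @param smiles Character vector.
#' @return Numeric vector (NA for unparseable input).
#' @export
chem_qed <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  res <- chem_call("qed", list(smiles = smiles))
  vapply(res, function(r) if (isTRUE(r$ok)) r$qed else NA_real_, 0)
}

#' Match SMARTS patterns against molecules
#'
#' @param smiles Character vector of molecules.
#' @param smarts Character vector of SMARTS patterns.
#' @return List (per molecule) of lists (per pattern) with elements
#'   `n_matches` and `atoms` (1-based union of matched atom indices).
#' @export
chem_smarts_matches <- function(smiles, smarts) {
  stopifnot(is.character(smiles), is.character(smarts),
            length(smiles) >= 1, length(smarts) >= 1)
  res <- chem_call("smarts", list(smiles = smiles, smarts = smarts))
  lapply(res, function(r) {
    if (!isTRUE(r$ok)) stop("unparseable structure in SMARTS matching")
    lapply(r$patterns, function(p)
      list(n_matches = p$n_matches, atoms = as.integer(unlist(p$atoms))))
  })
}

#' Render a molecule as SVG with per-atom highlight intensities (internal).
#' @keywords internal
chem_render_svg <- function(smiles, weights, out, width = 450, height = 400) {
  res <- chem_call("render", list(smiles = smiles, weights = as.numeric(weights),
                                  out = out, width = width, height = height))
  if (!isTRUE(res$ok)) stop("render failed: ", res$reason)
  invisible(out)
}
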