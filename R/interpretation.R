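#' @title Atom-level interpretation
#' @description Extracts per-atom importance weights from a trained model
#'   (readout attention or gradient saliency), min-max normalizes them per
#'   molecule, calls key atoms (weight above the molecule average), and
#'   tests whether a chosen substructure carries significantly higher
#'   weights than the rest of the molecule with a one-sided rank-sum test.
#' @name interpretation
NULL

#' Raw per-atom importance weights for one molecule
#'
#' Two attribution routes share this interface:
#' \describe{
#'   \item{`readout_attention`}{the attentive-readout weights, averaged over
#'     readout timesteps; nonnegative, summing to 1 over the molecule. The
#'     readout attends to atoms when building the molecule embedding, so
#'     these weights do not depend on the chosen head.}
#'   \item{`gradient`}{L2 norm, per atom, of the gradient of the selected
#'     head outputs (summed) with respect to the final atom states.}
#' }
#'
#' @param model Trained `mt_model`.
#' @param smiles Single SMILES string (or a `molecular_graph`).
#' @param method `"readout_attention"` (default) or `"gradient"`.
#' @param target Target name(s) for the gradient route, or `"mean"` (all
#'   heads averaged).
#' @return Numeric vector of nonnegative weights, one per atom.
#' @export
atom_weights <- function(model, smiles,
                         method = c("readout_attention", "gradient"),
                         target = "mean") {
  method <- match.arg(method)
  batch <- as_graph_batch(smiles, model$schema)
  if (length(batch$n_atoms) != 1) stop("atom_weights expects a single molecule")
  fw <- mt_forward(batch, model, keep_cache = TRUE)
  if (method == "readout_attention") {
    att <- vapply(fw$cache$reads, function(rc) rc$align,
                  numeric(batch$n_atoms[1]))
    if (batch$n_atoms[1] == 1) att <- matrix(att, nrow = 1)
    return(rowMeans(att))
  }
  tnames <- model$config$targets
  wsel <- if (identical(target, "mean")) {
    rep(1 / length(tnames), length(tnames))
  } else {
    sel <- tnames %in% target
    if (!any(sel)) stop("unknown target: ", paste(target, collapse = ","))
    as.numeric(sel)
  }
  dpred <- matrix(wsel, nrow = 1)
  g <- mt_backward(fw, dpred, model, return_datom = TRUE)
  sqrt(rowSums(g$datom^2))
}

#' Min-max normalize atom weights per molecule
#'
#' Maps the weight vector onto `[0, 1]`; a constant vector (no contrast)
#' maps to all 0.5.
#'
#' @param raw Numeric vector of raw weights.
#' @return Normalized weights.
#' @export
normalize_weights <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1)
  rng <- range(raw)
  if (diff(rng) == 0) return(rep(0.5, length(raw)))
  (raw - rng[1]) / diff(rng)
}

#' Full atom attribution for one molecule
#'
#' @inheritParams atom_weights
#' @return `atom_attribution` list: `smiles`, `raw_weights`,
#'   `normalized_weights`, `molecule_mean` (of normalized weights),
#'   `key_atoms` (indices with normalized weight strictly above the
#'   molecule mean).
#' @export
atom_attribution <- function(model, smiles,
                             method = c("readout_attention", "gradient"),
                             target = "mean") {
  raw <- atom_weights(model, smiles, method, target)
  norm <- normalize_weights(raw)
  structure(list(smiles = if (is.character(smiles)) smiles else NA_character_,
                 raw_weights = raw, normalized_weights = norm,
                 molecule_mean = mean(norm),
                 key_atoms = which(norm > mean(norm)),
                 method = match.arg(method)),
            class = "atom_attribution")
}

rank_sum_statistic <- function(a, b) {
  sum(rank(c(a, b))[seq_along(a)])
}

#' One-sided rank-sum test that a substructure outweighs the rest
#'
#' Tests H1: the atom weights in region A are stochastically greater than
#' the weights of the remaining atoms B. For molecules with at most
#' `exact_max` atoms the permutation distribution of the rank-sum statistic
#' is enumerated exhaustively (exact even under ties); larger molecules use
#' the normal approximation with tie correction and continuity correction.
#'
#' @param weights Numeric vector of atom weights for the whole molecule.
#' @param region Integer indices of the substructure atoms (set A).
#' @param exact_max Size limit for exhaustive enumeration.
#' @return `substructure_test` list: `region_atoms`, `region_mean`,
#'   `complement_mean`, `statistic` (rank sum of A), `p_value`,
#'   `significant` (p < 0.05), `method`.
#' @export
rank_sum_region_test <- function(weights, region, exact_max = 12L) {
  n <- length(weights)
  region <- sort(unique(as.integer(region)))
  if (length(region) < 1 || length(region) >= n) {
    stop("region must be a non-empty proper subset of atoms")
  }
  if (any(region < 1 | region > n)) stop("region indices out of range")
  a <- weights[region]
  b <- weights[-region]
  w_obs <- rank_sum_statistic(a, b)
  na <- length(a)
  if (n <= exact_max) {
    rk <- rank(weights)
    combos <- utils::combn(n, na)
    stats <- colSums(matrix(rk[combos], nrow = na))
    p <- mean(stats >= w_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    rk <- rank(weights)
    mu <- na * (n + 1) / 2
    ties <- table(weights)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * (n - na) / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w_obs - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(region_atoms = region, region_mean = mean(a),
                 complement_mean = mean(b), statistic = w_obs,
                 p_value = p, significant = p < 0.05, method = method),
            class = "substructure_test")
}

#' Test a SMARTS-defined region of a molecule
#'
#' Convenience wrapper: matches a SMARTS pattern, takes the union of matched
#' atoms as region A, and runs [rank_sum_region_test()] on the attribution
#' weights (normalized and raw means are both reported, since min-max
#' scaling changes means but not ranks).
#'
#' @param model Trained `mt_model`.
#' @param smiles Molecule.
#' @param smarts Substructure pattern.
#' @param method Attribution route, see [atom_weights()].
#' @return `substructure_test` with extra fields `raw_region_mean`,
#'   `raw_complement_mean`, or NULL when the pattern does not match.
#' @export
test_substructure <- function(model, smiles, smarts,
                              method = c("readout_attention", "gradient")) {
  m <- chem_smarts_matches(smiles, smarts)[[1]][[1]]
  if (m$n_matches == 0) return(NULL)
  att <- atom_attribution(model, smiles, method)
  out <- rank_sum_region_test(att$normalized_weights, m$atoms)
  out$raw_region_mean <- mean(att$raw_weights[m$atoms])
  out$raw_complement_mean <- mean(att$raw_weights[-m$atoms])
  out
}

#' Render an attribution as an SVG depiction plus a weight table
#'
#' Atoms are shaded with intensity proportional to their normalized weight
#' (darker = more important). The CSV table (atom index, element, raw and
#' normalized weight, key-atom flag) is always written, even if depiction
#' fails.
#'
#' @param attribution `atom_attribution` (with a `smiles` field).
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return Invisible list of written paths (`svg` may be NA on failure).
#' @export
render_attribution <- function(attribution, out_dir, name = "attribution") {
  stopifnot(inherits(attribution, "atom_attribution"),
            is.character(attribution$smiles), !is.na(attribution$smiles))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  percept <- chem_perceive(attribution$smiles)[[1]]
  tab <- data.frame(
    atom_index = seq_along(attribution$raw_weights),
    element = vapply(percept$atoms, function(a) a$symbol, ""),
    raw_weight = attribution$raw_weights,
    normalized_weight = attribution$normalized_weights,
    key_atom = seq_along(attribution$raw_weights) %in% attribution$key_atoms)
  csv_path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(tab, csv_path, row.names = FALSE)
  svg_path <- file.path(out_dir, paste0(name, ".svg"))
  svg_ok <- tryCatch({
    chem_render_svg(attribution$smiles, attribution$normalized_weights, svg_path)
    TRUE
  }, error = function(e) {
    warning("depiction failed: ", conditionMessage(e))
    FALSE
  })
  invisible(list(csv = csv_path, svg = if (svg_ok) svg_path else NA_character_,
                 table = tab))
}
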