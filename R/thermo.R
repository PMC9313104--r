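## ITC-derived thermodynamics: Kd / Gibbs energy / entropy-term derivation,
## reconciliation against published tables, state similarity and
## co-ligand competition checks.

## Gas constant in kcal mol^-1 K^-1.
R_KCAL <- 1.9872e-3

#' Construct an ITC thermodynamic state
#'
#' One receptor state characterized by its association constant and binding
#' enthalpy from isothermal titration calorimetry. Either `Ka` (M^-1) or
#' `Kd_uM` (micromolar) may be given.
#'
#' @param state state label (e.g. `"E1"`, `"E2P"`, `"OBN"`).
#' @param Ka association constant, M^-1 (> 0).
#' @param dH binding enthalpy, kcal/mol.
#' @param T temperature in kelvin (default 298.15, i.e. 25 degrees C).
#' @param n binding stoichiometry (default 1).
#' @param Kd_uM alternative to `Ka`: dissociation constant in micromolar.
#' @return An object of class `thermo_state`.
#' @export
thermo_state <- function(state, Ka = NULL, dH = NA_real_, T = 298.15, n = 1,
                         Kd_uM = NULL) {
  if (is.null(Ka) == is.null(Kd_uM))
    stopf("give exactly one of Ka or Kd_uM")
  if (is.null(Ka)) Ka <- 1e6 / Kd_uM
  if (!is.finite(Ka) || Ka <= 0) stopf("Ka must be > 0 (got %s)", format(Ka))
  if (T <= 0) stopf("temperature must be > 0 K")
  structure(list(state = state, Ka = Ka, dH = dH, T = T, n = n),
            class = "thermo_state")
}

#' Derive Kd, Gibbs energy and entropy term for a state
#'
#' Applies the standard relations `dG = -R T ln(Ka)` and `dG = dH - TdS`
#' with R = 1.9872e-3 kcal/(mol K): `Kd = 1/Ka` (reported in micromolar),
#' `TdS = dH - dG`. Values are kept at full precision; use
#' [format_thermo()] for table-style presentation rounding.
#'
#' @param state a `thermo_state`.
#' @return A one-row `data.frame` of class `thermo_derived`: `state`, `Ka`,
#'   `Kd_uM`, `dH`, `dG`, `TdS`, `T`.
#' @export
derive_thermo <- function(state) {
  dG <- -R_KCAL * state$T * log(state$Ka)
  structure(data.frame(state = state$state, Ka = state$Ka,
                       Kd_uM = 1e6 / state$Ka, dH = state$dH, dG = dG,
                       TdS = state$dH - dG, T = state$T),
            class = c("thermo_derived", "data.frame"))
}

#' Presentation rounding for derived thermodynamics
#'
#' Kd to 2 significant figures, energies to 2 decimals — the conventional
#' ITC table format.
#'
#' @param derived a `thermo_derived` data frame (one or more rows).
#' @return A data frame with rounded `Kd_uM`, `dG`, `TdS`, `dH` columns.
#' @export
format_thermo <- function(derived) {
  data.frame(state = derived$state,
             Kd_uM = signif(derived$Kd_uM, 2L),
             dH = round(derived$dH, 2L),
             TdS = round(derived$TdS, 2L),
             dG = round(derived$dG, 2L))
}

#' Derive thermodynamics for a table of states
#'
#' @param df data frame with columns `state`, `Ka` (or `Kd_uM`), `dH` and
#'   optionally `T`.
#' @return Row-bound [derive_thermo()] results.
#' @export
thermo_table <- function(df) {
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    derive_thermo(thermo_state(
      state = df$state[i],
      Ka = if ("Ka" %in% names(df)) df$Ka[i] else NULL,
      Kd_uM = if (!"Ka" %in% names(df) && "Kd_uM" %in% names(df)) df$Kd_uM[i] else NULL,
      dH = if ("dH" %in% names(df)) df$dH[i] else NA_real_,
      T = if ("T" %in% names(df)) df$T[i] else 298.15))
  }))
}

#' Read an ITC state table from TSV
#'
#' Expected columns: `state`, `Ka` (M^-1) or `Kd_uM`, `dH` (kcal/mol),
#' optional `T` (K) and printed `dG`/`TdS` columns for reconciliation.
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_thermo_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Reconcile derived thermodynamics against a printed table
#'
#' Published ITC tables print rounded Ka, Kd, dH, TdS and dG; recomputing
#' the derived cells from the printed Ka can therefore disagree slightly
#' with the printed dG. This routine recomputes every derivable cell and
#' flags, rather than resolves, internal inconsistencies:
#' \itemize{
#'   \item `Kd_calc` = 1/Ka at 2 significant figures vs printed `Kd_uM`;
#'   \item `dG_calc` = -RT ln(Ka) at 2 decimals vs printed `dG`, flagged
#'     when the difference exceeds `tolerance` (default 0.02 kcal/mol,
#'     the slack a Ka rounded to 2 significant figures can introduce);
#'   \item `TdS_calc` = dH - printed dG at 2 decimals vs printed `TdS`
#'     (the published derivation path for the entropy column).
#' }
#'
#' @param printed data frame with columns `state`, `Ka`, `Kd_uM`, `dH`,
#'   `TdS`, `dG` and optionally `T`.
#' @param tolerance dG reconciliation tolerance in kcal/mol (default 0.02).
#' @return A data frame of class `thermo_reconciliation` with `*_calc`
#'   columns and logical `kd_match`, `dG_match`, `tds_match` flags plus
#'   `dG_diff`.
#' @export
reconcile_thermo <- function(printed, tolerance = 0.02) {
  derived <- thermo_table(printed)
  eps <- 1e-9
  out <- data.frame(
    state = printed$state,
    Kd_uM = printed$Kd_uM, Kd_calc = signif(derived$Kd_uM, 2L),
    dG = printed$dG, dG_calc = round(derived$dG, 2L),
    TdS = printed$TdS, TdS_calc = round(printed$dH - printed$dG, 2L))
  out$kd_match <- abs(out$Kd_calc - out$Kd_uM) < eps
  out$dG_diff <- out$dG_calc - out$dG
  out$dG_match <- abs(out$dG_diff) <= tolerance + eps
  out$tds_match <- abs(out$TdS_calc - out$TdS) < eps
  structure(out, class = c("thermo_reconciliation", "data.frame"),
            tolerance = tolerance)
}

#' @export
print.thermo_reconciliation <- function(x, ...) {
  cat(sprintf("thermo_reconciliation (+/- %.2f kcal/mol on dG):\n",
              attr(x, "tolerance")))
  for (i in seq_len(nrow(x))) {
    flag <- if (x$dG_match[i] && x$kd_match[i] && x$tds_match[i]) "ok"
            else "INCONSISTENT"
    cat(sprintf("  %-6s Kd %.2g/%.2g  dG %.2f/%.2f (diff %+.2f)  TdS %.2f/%.2f  %s\n",
                x$state[i], x$Kd_uM[i], x$Kd_calc[i], x$dG[i], x$dG_calc[i],
                x$dG_diff[i], x$TdS[i], x$TdS_calc[i], flag))
  }
  invisible(x)
}

#' Compare thermodynamic states for similarity
#'
#' Computes the maximum pairwise differences in Gibbs energy (and enthalpy,
#' when available) across states and calls the set "similar" when the
#' maximum |ddG| does not exceed `tolerance`. The default tolerance of
#' 0.6 kcal/mol corresponds to roughly a +/-20 percent uncertainty on Ka
#' at 25 degrees C.
#'
#' @param states list of `thermo_state`s, a `thermo_derived`-style data
#'   frame with a `dG` column, or a numeric vector of dG values.
#' @param tolerance similarity tolerance on |ddG| in kcal/mol (default 0.6).
#' @return list(max_ddG, max_ddH, similar, dG) of class
#'   `thermo_similarity`.
#' @export
compare_states <- function(states, tolerance = 0.6) {
  if (is.numeric(states)) {
    dG <- states; dH <- NULL
  } else if (is.data.frame(states)) {
    dG <- states$dG; dH <- states$dH
  } else {
    derived <- do.call(rbind, lapply(states, derive_thermo))
    dG <- derived$dG; dH <- derived$dH
  }
  if (length(dG) < 2L) stopf("need >= 2 states to compare")
  out <- list(max_ddG = max(dG) - min(dG),
              max_ddH = if (!is.null(dH) && all(is.finite(dH)))
                max(dH) - min(dH) else NA_real_,
              similar = (max(dG) - min(dG)) <= tolerance,
              tolerance = tolerance, dG = dG)
  class(out) <- "thermo_similarity"
  out
}

#' @export
print.thermo_similarity <- function(x, ...) {
  cat(sprintf("thermo_similarity: max |ddG| %.2f kcal/mol (tolerance %.2f) -> %s\n",
              x$max_ddG, x$tolerance,
              if (x$similar) "similar" else "not similar"))
  if (is.finite(x$max_ddH))
    cat(sprintf("  max |ddH| %.2f kcal/mol\n", x$max_ddH))
  invisible(x)
}

#' Does a co-ligand change binding thermodynamics?
#'
#' Compares the derived Gibbs energy of a ligand binding to the free
#' receptor vs the receptor in complex with another ligand; within
#' `tolerance` the binding is called unchanged (no competition).
#'
#' @param free,in_complex `thermo_state`s of the two measurements.
#' @param tolerance |ddG| tolerance in kcal/mol (default 0.6).
#' @return list(ddG, unchanged, free, in_complex).
#' @export
competition_check <- function(free, in_complex, tolerance = 0.6) {
  a <- derive_thermo(free); b <- derive_thermo(in_complex)
  ddG <- abs(a$dG - b$dG)
  list(ddG = ddG, unchanged = ddG <= tolerance,
       free = a, in_complex = b)
}

#' Write derived thermodynamics
#'
#' @param derived a `thermo_derived` data frame.
#' @param path output path (`.tsv` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_thermo <- function(derived, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(as.data.frame(derived), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else
    utils::write.table(as.data.frame(derived), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
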