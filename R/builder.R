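#' Plan a random lipid exchange from a POPC template bilayer
#'
#' Converts a pure-POPC bilayer into a target composition by random
#' replacement, leaflet by leaflet: one POPC is consumed per new POPE or
#' POPG, and two POPC per cardiolipin (whose two diacylphosphatidic-acid
#' halves each take a POPC slot). Assignment is uniformly random under the
#' seed and deterministic given it; unconsumed POPC remain POPC.
#'
#' @param popc_ids named list \code{list(INNER = ids, OUTER = ids)} of POPC
#'   molecule_ids per leaflet.
#' @param targets named list per leaflet of named target counts, e.g.
#'   \code{list(INNER = c(POPE = 14, POPG = 4, CL = 1))}; empty requests are
#'   allowed.
#' @param seed integer seed.
#' @return object of class \code{exchange_plan}: per leaflet a data.frame
#'   (molecule_id, new_species, cl_pair) plus resulting per-species counts.
#' @export
plan_lipid_exchange <- function(popc_ids, targets, seed = 1L) {
  set.seed(as.integer(seed))
  plan <- list()
  counts <- list()
  for (lf in names(popc_ids)) {
    ids <- popc_ids[[lf]]
    want <- targets[[lf]]
    if (is.null(want)) want <- numeric(0)
    want <- want[want > 0]
    need <- sum(want[setdiff(names(want), "CL")]) +
      2 * sum(want[names(want) == "CL"])
    if (need > length(ids))
      stop("leaflet ", lf, ": need ", need, " POPC but only ",
           length(ids), " available (shortfall ", need - length(ids), ")")
    pool <- sample(ids, need)
    rows <- list(); used <- 0L; pair <- 0L
    for (sp in names(want)) {
      k <- want[[sp]]
      for (j in seq_len(k)) {
        if (sp == "CL") {
          pair <- pair + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            molecule_id = pool[used + 1:2], new_species = "CL",
            cl_pair = pair, stringsAsFactors = FALSE)
          used <- used + 2L
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            molecule_id = pool[used + 1L], new_species = sp,
            cl_pair = NA_integer_, stringsAsFactors = FALSE)
          used <- used + 1L
        }
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(molecule_id = integer(), new_species = character(),
                 cl_pair = integer(), stringsAsFactors = FALSE)
    leftover <- setdiff(ids, tab$molecule_id)
    cnt <- c(as.list(want), list(POPC = length(leftover)))
    plan[[lf]] <- tab
    counts[[lf]] <- unlist(cnt)
  }
  structure(list(replacements = plan, counts = counts, seed = seed),
            class = "exchange_plan")
}

#' Neutralizing-ion arithmetic
#'
#' Balances the net charge of the system with monovalent salt: the Na+/Cl-
#' difference must cancel the summed charge contributions (anionic lipids,
#' protein net charge). Either the Cl- count is fixed (e.g. set elsewhere by
#' a target salt concentration) and Na+ follows, or a salt specification
#' (molarity and water count) chooses Cl- as round(molarity * water_count /
#' 55.5) first.
#'
#' @param charge_contributions integer charges in units of e (e.g. the POPG
#'   total, the CL total, the protein net charge).
#' @param n_cl fixed number of Cl- ions.
#' @param salt_molarity,water_count alternative to \code{n_cl}.
#' @return object of class \code{ion_counts}: list(n_na, n_cl,
#'   residual_charge_e) with residual always exactly 0 on success.
#' @export
neutralizing_ions <- function(charge_contributions, n_cl = NULL,
                              salt_molarity = NULL, water_count = NULL) {
  q <- sum(as.integer(round(charge_contributions)))
  if (is.null(n_cl)) {
    if (is.null(salt_molarity) || is.null(water_count))
      stop("give n_cl, or salt_molarity together with water_count")
    n_cl <- round(salt_molarity * water_count / 55.5)
  }
  n_na <- n_cl - q
  if (n_na < 0 || n_cl < 0)
    stop("neutralization impossible: would need ", n_na, " Na+ and ",
         n_cl, " Cl-")
  structure(list(n_na = as.integer(n_na), n_cl = as.integer(n_cl),
                 residual_charge_e = as.integer(q + n_na - n_cl)),
            class = "ion_counts")
}
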