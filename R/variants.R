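# Charge-variant bookkeeping for the folded domain.

#' Charge-variant reference table
#'
#' Loads the shipped table of globular-domain charge variants: net
#' charge, melting temperature, relative CSP sum and apparent Kd
#' (uM). Variants too weak for a titration fit have NA Kd.
#'
#' @return data.frame with columns variant, substitutions, net_charge,
#'   tm_K, tm_se_K, rel_csp_sum, rel_csp_sum_se, kd_uM, kd_se_uM.
#' @export
gd_variants <- function() {
  path <- system.file("extdata", "gd_variants.tsv", package = "polybind")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Net charge of a chain-ligand complex
#'
#' Charge bookkeeping for a 1:n complex between the polyanionic chain
#' and n copies of a cationic ligand.
#'
#' @param n_ligands ligands bound.
#' @param q_ligand net charge per ligand (default +9, the wild-type
#'   globular domain).
#' @param q_chain net charge of the chain (default -44).
#' @return list: \code{q_ligands} (summed ligand charge) and
#'   \code{q_complex} (total complex charge).
#' @export
complex_net_charge <- function(n_ligands, q_ligand = 9, q_chain = -44) {
  if (n_ligands < 0) stop_input("n_ligands must be >= 0")
  ql <- n_ligands * q_ligand
  list(q_ligands = ql, q_complex = q_chain + ql)
}

#' Affinity fold change between two charge variants
#'
#' Ratio of apparent dissociation constants between two named variants
#' of the reference table, with the corresponding net-charge
#' difference; quantifies the affinity change per unit of ligand net
#' charge.
#'
#' @param variant_weak,variant_strong variant names (weak = larger Kd).
#' @param table variant table (default [gd_variants()]).
#' @return list: \code{kd_ratio}, \code{delta_charge},
#'   \code{kd_weak_uM}, \code{kd_strong_uM}.
#' @export
kd_fold_change <- function(variant_weak, variant_strong,
                           table = gd_variants()) {
  row <- function(v) {
    i <- match(v, table$variant)
    if (is.na(i)) stop_input("unknown variant '%s'", v)
    table[i, ]
  }
  w <- row(variant_weak); s <- row(variant_strong)
  if (!is.finite(w$kd_uM) || !is.finite(s$kd_uM))
    stop_input("variant without a fitted Kd")
  list(kd_ratio = w$kd_uM / s$kd_uM,
       delta_charge = s$net_charge - w$net_charge,
       kd_weak_uM = w$kd_uM, kd_strong_uM = s$kd_uM)
}
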