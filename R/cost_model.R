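# Sanger-vs-WGS screening cost calculator.  Money is held as integer
# cents so per-strain components add exactly; the shipped defaults are
# the CAD figures for a 100-strain screen (Sanger: primers 0.40 + PCR
# 5.00 + purification 12.00 + sequencing 64.00 per strain, about 2.5
# days hands-on; WGS: DNA extraction 14 + sequencing 200 per strain,
# about 7 h hands-on) and every number is configurable.

#' Construct a cost profile
#'
#' @param method `"SANGER"` or `"WGS"` (a free label is allowed).
#' @param per_strain_components named numeric, currency units per strain
#'   per component; all `>= 0`.  Stored as integer cents.
#' @param hands_on_hours total hands-on time at `n_strains` strains.
#' @param n_strains number of strains.
#' @param currency display label.
#' @return object of class `CostProfile`.
#' @export
cost_profile <- function(method, per_strain_components, hands_on_hours,
                         n_strains, currency = "CAD") {
  if (any(per_strain_components < 0))
    stop_config("component costs must be >= 0")
  if (n_strains < 0) stop_config("n_strains must be >= 0")
  cents <- round(per_strain_components * 100)
  structure(list(method = method,
                 component_cents = setNames(as.integer(cents),
                                            names(per_strain_components)),
                 hands_on_hours = hands_on_hours,
                 n_strains = as.integer(n_strains), currency = currency),
            class = "CostProfile")
}

#' Default Sanger screening profile
#' @param n_strains number of strains (default 100).
#' @return a [cost_profile()].
#' @export
sanger_profile <- function(n_strains = 100) {
  cost_profile("SANGER",
               c(primers = 0.40, pcr = 5.00, purification = 12.00,
                 sanger_sequencing = 64.00),
               hands_on_hours = 2.5 * 24, n_strains = n_strains)
}

#' Default WGS screening profile
#' @param n_strains number of strains (default 100).
#' @return a [cost_profile()].
#' @export
wgs_profile <- function(n_strains = 100) {
  cost_profile("WGS",
               c(dna_extraction = 14.00, wgs_sequencing = 200.00),
               hands_on_hours = 7, n_strains = n_strains)
}

#' Total cost of a profile
#'
#' `n_strains` times the sum of per-strain components; exact decimal
#' arithmetic in cents.
#'
#' @param profile a [cost_profile()].
#' @return total in currency units.
#' @examples
#' total_cost(sanger_profile(100))  # 8140
#' @export
total_cost <- function(profile) {
  profile$n_strains * sum(profile$component_cents) / 100
}

per_strain_cost <- function(profile) sum(profile$component_cents) / 100

#' Compare two screening cost profiles
#'
#' Side-by-side totals, per-strain costs and hands-on times for two
#' profiles covering the same number of strains, with the standing
#' qualitative caveats: per-locus methods stay cheaper per strain but
#' scale with gene size and only see the target locus, while WGS also
#' reveals extragenic candidates and genomic background at a higher
#' up-front price.
#'
#' @param a,b two [cost_profile()]s with equal `n_strains`.
#' @return object of class `CostComparison`: list with `methods`,
#'   `totals`, `per_strain`, `hands_on_hours`, `n_strains`, `notes`.
#' @export
compare_costs <- function(a, b) {
  if (a$n_strains != b$n_strains)
    stop_config("profiles cover different strain counts (", a$n_strains,
                " vs ", b$n_strains, ")")
  structure(list(
    methods = c(a$method, b$method),
    totals = setNames(c(total_cost(a), total_cost(b)),
                      c(a$method, b$method)),
    per_strain = setNames(c(per_strain_cost(a), per_strain_cost(b)),
                          c(a$method, b$method)),
    hands_on_hours = setNames(c(a$hands_on_hours, b$hands_on_hours),
                              c(a$method, b$method)),
    n_strains = a$n_strains,
    currency = a$currency,
    notes = c(paste("Per-locus sequencing cost scales with gene size and",
                    "amplicon count; hard-to-amplify loci need",
                    "optimization."),
              paste("WGS additionally reveals extragenic candidates,",
                    "genomic burden and retention/reversion of the",
                    "primary lesion in the same data."),
              paste("Weak suppressors growing poorly may not yield",
                    "enough genomic DNA for WGS."))),
    class = "CostComparison")
}

#' @export
print.CostComparison <- function(x, ...) {
  cat("<CostComparison> n =", x$n_strains, "strains\n")
  for (m in names(x$totals))
    cat(sprintf("  %-8s total %10.2f %s (%.2f/strain), hands-on %.1f h\n",
                m, x$totals[[m]], x$currency, x$per_strain[[m]],
                x$hands_on_hours[[m]]))
  invisible(x)
}
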