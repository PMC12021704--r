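#' Intervention programme costing
#'
#' Per-participant programme costs under the delivery-mix scenarios used
#' in the economic evaluation. The intervention (DEW) costs a net £271 per
#' participant, £325 once UK VAT at 20% is added. The comparator
#' education programme (DE) is costed as a weighted average of
#' face-to-face and online delivery; the base mix is 57.6% face-to-face at
#' £265 and 42.4% online at £12, giving £158, and the optimistic-uptake
#' scenario uses £160.53 / £8.48 per person, giving £96.
#'
#' @param name Scenario label.
#' @param f2f_cost,online_cost Per-person component costs (GBP).
#' @param f2f_share Proportion delivered face-to-face, in `[0, 1]`.
#' @param vat_rate VAT rate applied where relevant (default 0.20).
#' @return An object of class `cost_scenario`.
#' @export
cost_scenario <- function(name, f2f_cost, online_cost, f2f_share,
                          vat_rate = 0.20) {
  if (f2f_cost < 0 || online_cost < 0) stop("component costs must be non-negative")
  if (f2f_share < 0 || f2f_share > 1) stop("f2f_share must lie in [0, 1]")
  structure(list(name = name, f2f_cost = f2f_cost,
                 online_cost = online_cost, f2f_share = f2f_share,
                 vat_rate = vat_rate),
            class = "cost_scenario")
}

#' Add VAT to a net cost
#'
#' @param base Net cost (GBP), non-negative.
#' @param vat_rate VAT rate (default 0.20, the UK standard rate).
#' @return `base * (1 + vat_rate)` rounded to the nearest pound.
#' @examples
#' cost_with_vat(271)  # 325
#' @export
cost_with_vat <- function(base, vat_rate = 0.20) {
  if (base < 0 || vat_rate < 0) stop("costs and VAT rate must be non-negative")
  round(base * (1 + vat_rate))
}

#' Weighted per-person programme cost of a delivery mix
#'
#' @param scenario A [cost_scenario()].
#' @return `f2f_share * f2f_cost + (1 - f2f_share) * online_cost` rounded
#'   to the nearest pound.
#' @examples
#' weighted_programme_cost(cost_scenario("mixed", 265, 12, 0.576))  # 158
#' @export
weighted_programme_cost <- function(scenario) {
  stopifnot(inherits(scenario, "cost_scenario"))
  round(scenario$f2f_share * scenario$f2f_cost +
          (1 - scenario$f2f_share) * scenario$online_cost)
}

#' Default costing scenarios
#'
#' The four delivery scenarios of the lifetime analysis: mixed, fully
#' face-to-face, fully online, and the optimistic-uptake costing of the
#' comparator, together with the fixed intervention cost.
#'
#' @return A data frame with columns `scenario`, `dew_cost`, `de_cost`.
#' @examples
#' cost_scenarios()
#' @export
cost_scenarios <- function() {
  dew <- cost_with_vat(271, 0.20)
  scen <- list(
    cost_scenario("mixed", 265, 12, 0.576),
    cost_scenario("f2f_only", 265, 12, 1),
    cost_scenario("online_only", 265, 12, 0),
    cost_scenario("optimistic_uptake", 160.53, 8.48, 0.576)
  )
  data.frame(
    scenario = vapply(scen, `[[`, "", "name"),
    dew_cost = dew,
    de_cost = vapply(scen, weighted_programme_cost, 0)
  )
}
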