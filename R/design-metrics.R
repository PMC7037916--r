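#' Percent change rate between a parent compound and a derivative
#'
#' Two conventions are used in the screening tables:
#' \describe{
#'   \item{`signed`}{`100 * (derivative - parent) / |parent|` — composites,
#'     logKow, half-lives, docking total scores.}
#'   \item{`magnitude`}{`100 * (|derivative| - |parent|) / |parent|` — used
#'     for negative-valued quantities (DFT total energies, docking binding
#'     energies) whose printed "increase" refers to growing magnitude.}
#' }
#'
#' @param parent,derivative numeric values; `parent` must be nonzero
#' @param convention `"signed"` or `"magnitude"`
#' @return percent change rate
#' @export
change_rate <- function(parent, derivative,
                        convention = c("signed", "magnitude")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(parent), is.finite(derivative))
  if (parent == 0) {
    stop_duotox("change rate undefined for parent value 0",
                class = "duotox_config_error")
  }
  if (convention == "signed") {
    100 * (derivative - parent) / abs(parent)
  } else {
    100 * (abs(derivative) - abs(parent)) / abs(parent)
  }
}

# metric -> convention used by the screening tables; magnitude for the
# negative-valued energies, signed elsewhere
METRIC_CONVENTION <- c(
  composite = "signed", frequency = "signed", total_energy = "magnitude",
  log_kow = "signed", t_half_river = "signed",
  dock_total_score = "signed", dock_binding_energy = "magnitude"
)

#' Single-toxicity change rates and their log-level ratio
#'
#' Change rates of the raw toxicity concentrations (EC50 toward green algae,
#' LOEC for bacterial genotoxicity: lower concentration = higher toxicity, so
#' rates are reported as `100 * (parent - derivative) / parent`) plus the
#' ratio of the two relative changes at logarithmic level:
#' `pEC50 = log10(EC50)`, `pLOEC = -log10(LOEC)`, relative change of each
#' `|p_deriv - p_parent| / p_parent`, and
#' `ratio = rel_dpEC50 / rel_dpLOEC`.
#'
#' Note the documented formula divides by the parent's log value, so the
#' ratio is *not* invariant to re-expressing the concentrations in other
#' units; inputs are EC50 as printed and LOEC in mol/L.
#'
#' @param parent,derivative length-2 numeric vectors `c(EC50, LOEC)`, all
#'   values strictly positive
#' @return list with `d_ec50_pct`, `d_loec_pct`, `rel_dp_ec50`,
#'   `rel_dp_loec`, `ratio` (NA with a warning when the pLOEC change is zero)
#' @export
toxicity_log_ratio <- function(parent, derivative) {
  stopifnot(length(parent) == 2L, length(derivative) == 2L,
            all(parent > 0), all(derivative > 0))
  d_ec50 <- 100 * (parent[1] - derivative[1]) / parent[1]
  d_loec <- 100 * (parent[2] - derivative[2]) / parent[2]
  p_ec50 <- log10(c(parent[1], derivative[1]))
  p_loec <- -log10(c(parent[2], derivative[2]))
  rel1 <- abs(p_ec50[2] - p_ec50[1]) / p_ec50[1]
  rel2 <- abs(p_loec[2] - p_loec[1]) / p_loec[1]
  ratio <- if (rel2 == 0) {
    warning("pLOEC change is zero; ratio undefined")
    NA_real_
  } else rel1 / rel2
  list(d_ec50_pct = d_ec50, d_loec_pct = d_loec,
       rel_dp_ec50 = rel1, rel_dp_loec = rel2, ratio = ratio)
}

#' Screen candidate derivatives by composite change rate
#'
#' Ranks candidates by the signed percent change of the double-activity
#' composite relative to the parent (composites are typically negative, so an
#' increase toward zero is an improvement); candidates whose composite did
#' not increase are flagged rejected.
#'
#' @param parent_composite parent compound's composite value (nonzero)
#' @param candidates named numeric vector of candidate composite values
#' @param properties optional property data.frame from
#'   [read_property_table()]; change rates are attached for every property a
#'   candidate and the parent share (parent rows identified by `parent_id`)
#' @param parent_id compound_id of the parent in `properties`
#' @return data.frame of class `modification_report`, sorted by
#'   `change_rate_pct` descending: `derivative_id`, `composite`,
#'   `change_rate_pct`, `improved`, plus one `<property>_change_pct` column
#'   per shared property
#' @export
screen_derivatives <- function(parent_composite, candidates,
                               properties = NULL, parent_id = NULL) {
  stopifnot(is.numeric(parent_composite), length(parent_composite) == 1L)
  if (length(candidates) == 0L) {
    out <- data.frame(derivative_id = character(0), composite = numeric(0),
                      change_rate_pct = numeric(0), improved = logical(0))
    class(out) <- c("modification_report", "data.frame")
    return(out)
  }
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  }
  rates <- vapply(candidates, change_rate, numeric(1),
                  parent = parent_composite, convention = "signed")
  out <- data.frame(derivative_id = names(candidates),
                    composite = unname(candidates),
                    change_rate_pct = unname(rates),
                    improved = unname(rates) > 0,
                    stringsAsFactors = FALSE)
  if (!is.null(properties) && !is.null(parent_id)) {
    for (prop in intersect(unique(properties$property_name),
                           names(METRIC_CONVENTION))) {
      pp <- properties[properties$property_name == prop, ]
      pv <- pp$value[match(parent_id, pp$compound_id)]
      if (is.na(pv)) next
      dv <- pp$value[match(out$derivative_id, pp$compound_id)]
      out[[paste0(prop, "_change_pct")]] <- ifelse(
        is.na(dv), NA_real_,
        vapply(dv, function(v) if (is.na(v)) NA_real_ else
          change_rate(pv, v, METRIC_CONVENTION[[prop]]), numeric(1)))
    }
  }
  out <- out[order(-out$change_rate_pct), ]
  rownames(out) <- NULL
  class(out) <- c("modification_report", "data.frame")
  out
}
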