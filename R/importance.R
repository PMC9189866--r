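# Per-country ecosystem-service importance: pooled catch shares of the six
# seagrass-dependent taxa, coastal-hazard coastline percentages, and the
# three-class {1, 3, 5} importance scores broadcast to grid cells via EEZs.

#' The six seagrass-dependent commercial taxa
#'
#' The taxa with the highest seagrass residency index, used to pool the
#' fisheries catch. Scorpaena is a group and is expanded to its three
#' representative species; group members are summed before pooling.
#'
#' @return named list: taxon label -> character vector of species names
#' @export
default_taxa <- function() {
  list(
    "Pagellus acarne" = "Pagellus acarne",
    "Pagellus erythurus" = "Pagellus erythurus",
    "Trisopterus minutus" = "Trisopterus minutus",
    "Melicertus kerathurus" = "Melicertus kerathurus",
    "Pecten maximus" = "Pecten maximus",
    "Scorpaena" = c("Scorpaena scrofa", "Scorpaena porcus", "Scorpaena notata")
  )
}

#' Per-country share of the pooled regional catch
#'
#' For each country, the annual tonnage of each taxon is averaged over the
#' reference years (absent (country, taxon, year) records count as zero
#' tonnage), the per-taxon means are pooled (summed) over the taxa, and the
#' pooled value is expressed as a percentage of the regional total. Shares
#' sum to 100 by construction.
#'
#' @param catch data.frame: `country_code`, `taxon`, `year`, `tonnes`
#' @param taxa taxa list ([default_taxa()]); species of a group are summed
#' @param years reference years (default 2014-2018)
#' @return named numeric vector: country code -> percent of regional catch
#' @export
eez_catch_share <- function(catch, taxa = default_taxa(), years = 2014:2018) {
  stopifnot(is.data.frame(catch),
            all(c("country_code", "taxon", "year", "tonnes") %in% names(catch)))
  if (any(catch$tonnes < 0 | !is.finite(catch$tonnes))) {
    stop_mesa("tonnes must be finite and non-negative")
  }
  species <- unlist(taxa, use.names = FALSE)
  sub <- catch[catch$taxon %in% species & catch$year %in% years, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_mesa("no catch records for the requested taxa/years")
  }
  # mean annual tonnage per (country, species) over the window, missing = 0:
  # sum over records / number of years, then pool over species
  pooled <- tapply(sub$tonnes, sub$country_code, sum) / length(years)
  total <- sum(pooled)
  if (total == 0) stop_mesa("regional catch of the requested taxa is zero")
  shares <- 100 * pooled / total
  out <- as.numeric(shares)
  names(out) <- names(shares)
  out
}

#' Importance thresholds
#'
#' @param pct_low,pct_high class boundaries in percent (defaults 5 and 20);
#'   a boundary value falls in the higher class
#' @return object of class `importance_thresholds`
#' @export
importance_thresholds <- function(pct_low = 5, pct_high = 20) {
  if (!(0 < pct_low && pct_low < pct_high && pct_high < 100)) {
    stop_mesa("need 0 < pct_low < pct_high < 100")
  }
  structure(list(pct_low = pct_low, pct_high = pct_high),
            class = "importance_thresholds")
}

#' Convert a percentage into a three-class importance score
#'
#' Below `pct_low` percent scores 1 (very low), from `pct_low` up to (but
#' not including) `pct_high` scores 3 (moderate), and `pct_high` or more
#' scores 5 (very high). The coarse three-class scale reflects that national
#' percentages are far less granular than the susceptibility inputs.
#'
#' @param pct percentage in `[0, 100]`
#' @param thresholds an [importance_thresholds()]
#' @return integer score in {1, 3, 5}
#' @examples
#' score_importance(1)   # 1
#' score_importance(10)  # 3
#' score_importance(25)  # 5
#' @export
score_importance <- function(pct, thresholds = importance_thresholds()) {
  if (!is.finite(pct) || pct < 0 || pct > 100) {
    stop_mesa("pct must lie in [0, 100], got ", format(pct))
  }
  if (pct < thresholds$pct_low) 1L
  else if (pct < thresholds$pct_high) 3L
  else 5L
}

#' Build the per-country importance table
#'
#' Scores every country for both criteria: coastal hazards (percent of
#' coastline at very-high risk) and fisheries (pooled catch share of the
#' seagrass-dependent taxa). A country present in only one input gets score
#' 1 for the other criterion, with a warning.
#'
#' @param catch catch data.frame (see [eez_catch_share()])
#' @param risk data.frame: `country_code`, `pct_very_high_risk` in `[0, 100]`
#' @param taxa taxa list
#' @param years catch reference years
#' @param thresholds an [importance_thresholds()]
#' @return data.frame: `country_code`, `catch_share_pct`, `risk_pct`,
#'   `fisheries_score`, `hazard_score`
#' @export
build_importance_table <- function(catch, risk, taxa = default_taxa(),
                                   years = 2014:2018,
                                   thresholds = importance_thresholds()) {
  stopifnot(is.data.frame(risk),
            all(c("country_code", "pct_very_high_risk") %in% names(risk)))
  if (any(risk$pct_very_high_risk < 0 | risk$pct_very_high_risk > 100)) {
    stop_mesa("pct_very_high_risk must lie in [0, 100]")
  }
  shares <- eez_catch_share(catch, taxa, years)
  countries <- sort(union(names(shares), risk$country_code))
  only_one <- c(setdiff(names(shares), risk$country_code),
                setdiff(risk$country_code, names(shares)))
  if (length(only_one) > 0) {
    warn_mesa("country(ies) present in only one input, other criterion scored 1: ",
              paste(sort(only_one), collapse = ", "))
  }
  share_pct <- ifelse(countries %in% names(shares), shares[countries], 0)
  risk_pct <- risk$pct_very_high_risk[match(countries, risk$country_code)]
  risk_pct[is.na(risk_pct)] <- 0
  data.frame(
    country_code = countries,
    catch_share_pct = as.numeric(share_pct),
    risk_pct = risk_pct,
    fisheries_score = vapply(share_pct, score_importance, integer(1),
                             thresholds = thresholds),
    hazard_score = vapply(risk_pct, score_importance, integer(1),
                          thresholds = thresholds),
    stringsAsFactors = FALSE
  )
}

#' Broadcast per-country importance scores to grid cells
#'
#' Each cell inherits the score of the country its centroid falls in.
#' Cells with no EEZ assignment, or in a country absent from the table,
#' receive score 1 with a warning.
#'
#' @param table importance table ([build_importance_table()])
#' @param cell_to_eez data.frame `cell_id`, `country_code`
#'   ([assign_cells_to_eez()])
#' @param criterion `"hazard"` or `"fisheries"`
#' @return named integer vector: cell_id -> score in {1, 3, 5}
#' @export
importance_per_cell <- function(table, cell_to_eez,
                                criterion = c("hazard", "fisheries")) {
  criterion <- match.arg(criterion)
  col <- paste0(criterion, "_score")
  idx <- match(cell_to_eez$country_code, table$country_code)
  scores <- table[[col]][idx]
  orphan <- is.na(scores)
  if (any(orphan)) {
    warn_mesa(sum(orphan), " cell(s) without EEZ/importance assignment scored 1")
    scores[orphan] <- 1L
  }
  names(scores) <- cell_to_eez$cell_id
  scores
}
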