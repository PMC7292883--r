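## Phenotype-microarray style growth screens (Biolog PM1/PM2 carbon plates,
## PM3 nitrogen plates), growth calling and confusion statistics.

#' Describe one screening condition
#'
#' @param source exchange metabolite id of the probed source (without the
#'   EX_ prefix), e.g. \code{"glc__D_e"}.
#' @param role \code{"carbon"} or \code{"nitrogen"}. Nitrogen screens fix
#'   pyruvate as the sole carbon source, as in the plate protocol.
#' @param mode nitrogen regime: \code{"non-diazotrophic"} (ammonium open,
#'   N2 closed) or \code{"diazotrophic"} (N2 open, ammonium closed). The
#'   two regimes are exclusive.
#' @param uptake uptake bound for the probed source (mmol/gDW/h; the screen
#'   default of 10 stands in for plate-level estimates).
#' @param id optional condition label.
#' @return object of class \code{screen_condition}.
#' @export
screen_condition <- function(source, role = c("carbon", "nitrogen"),
                             mode = c("non-diazotrophic", "diazotrophic"),
                             uptake = 10, id = NULL) {
  role <- match.arg(role); mode <- match.arg(mode)
  structure(list(source = source, role = role, mode = mode,
                 uptake = uptake,
                 id = if (is.null(id)) paste(source, role, mode, sep = "|")
                      else id),
            class = "screen_condition")
}

## classify each exchanged metabolite by elemental content
.exchange_classes <- function(model) {
  E <- element_matrix(model)
  bids <- boundary_ids(model)
  mets <- vapply(model$reactions[bids], function(r) names(r$stoich), "")
  hasC <- !is.na(E["C", mets]) & E["C", mets] > 0
  hasN <- if ("N" %in% rownames(E)) !is.na(E["N", mets]) & E["N", mets] > 0
          else rep(FALSE, length(mets))
  # CO2 is not an organic carbon source
  organicC <- hasC & !(mets %in% "co2_e")
  data.frame(rid = bids, met = mets, organic_carbon = unname(organicC),
             nitrogenous = unname(hasN), stringsAsFactors = FALSE)
}

.find_exchange <- function(model, met) {
  bids <- boundary_ids(model)
  hit <- bids[vapply(model$reactions[bids],
                     function(r) identical(names(r$stoich), met), logical(1))]
  if (length(hit)) hit[1] else NA_character_
}

#' Build the medium for a screening condition
#'
#' Carbon role: every organic-carbon uptake other than the probed source is
#' closed and the source opened at its uptake bound. Nitrogen role:
#' pyruvate is opened as the sole carbon source, every other nitrogenous
#' uptake (including ammonium and N2) is closed and the probed source is
#' the sole nitrogen supply. In carbon screens the nitrogen regime opens
#' ammonium (non-diazotrophic) or N2 (diazotrophic, uptake left
#' unconstrained at the default cap) exclusively. Mineral exchanges (no C,
#' no N) always stay open. A probed source whose exchange reaction is
#' absent from the model is excluded with a reason code, mirroring how
#' plate compounds not identified in a reconstruction are dropped from
#' validation.
#'
#' @param model a \code{metabolic_model}.
#' @param cond a [screen_condition()].
#' @param pyruvate_uptake carbon bound used for pyruvate in nitrogen
#'   screens.
#' @return a [medium_spec()], or an object of class
#'   \code{screen_exclusion} (fields \code{id}, \code{reason}) when the
#'   source is not in the model.
#' @export
build_condition <- function(model, cond, pyruvate_uptake = 10) {
  stopifnot(inherits(cond, "screen_condition"))
  src_ex <- .find_exchange(model, cond$source)
  if (is.na(src_ex))
    return(structure(list(id = cond$id, reason = "not in model"),
                     class = "screen_exclusion"))
  cls <- .exchange_classes(model)
  med <- list()
  nh4_ex <- .find_exchange(model, "nh4_e")
  n2_ex <- .find_exchange(model, "n2_e")
  pyr_ex <- .find_exchange(model, "pyr_e")
  for (i in seq_len(nrow(cls))) {
    rid <- cls$rid[i]
    if (rid %in% c(src_ex, nh4_ex, n2_ex)) next
    if (cond$role == "nitrogen" && identical(rid, pyr_ex)) next
    if (cls$organic_carbon[i] || cls$nitrogenous[i])
      med[[rid]] <- c(0, 1000)          # closed to uptake
    else
      med[[rid]] <- c(-1000, 1000)      # mineral base stays open
  }
  med[[src_ex]] <- c(-abs(cond$uptake), 1000)
  if (cond$role == "nitrogen" && !identical(src_ex, pyr_ex)) {
    if (is.na(pyr_ex)) stop("nitrogen screens need a pyruvate exchange")
    med[[pyr_ex]] <- c(-abs(pyruvate_uptake), 1000)
  }
  if (cond$role == "nitrogen") {
    # the probed source is the sole nitrogen source
    if (!is.na(nh4_ex) && !identical(src_ex, nh4_ex)) med[[nh4_ex]] <- c(0, 1000)
    if (!is.na(n2_ex) && !identical(src_ex, n2_ex)) med[[n2_ex]] <- c(0, 1000)
  } else if (cond$mode == "non-diazotrophic") {
    if (!is.na(nh4_ex) && !identical(src_ex, nh4_ex)) med[[nh4_ex]] <- c(-1000, 1000)
    if (!is.na(n2_ex) && !identical(src_ex, n2_ex)) med[[n2_ex]] <- c(0, 1000)
  } else {
    if (!is.na(nh4_ex) && !identical(src_ex, nh4_ex)) med[[nh4_ex]] <- c(0, 1000)
    if (!is.na(n2_ex)) med[[n2_ex]] <- c(-1000, 1000)
  }
  medium_spec(.list = med)
}

#' Run a growth screen over a set of conditions
#'
#' One FBA per condition; infeasible conditions are recorded as zero growth
#' with a flag. Results are keyed and ordered by condition id, so permuting
#' the input leaves the content unchanged.
#'
#' @param model a \code{metabolic_model}.
#' @param conditions list of [screen_condition()]s.
#' @param threshold growth-call threshold passed to [call_growth()].
#' @return data.frame: \code{id}, \code{source}, \code{role}, \code{mode},
#'   \code{mu} (1/h), \code{status}, \code{excluded}, \code{grew}.
#' @export
run_screen <- function(model, conditions, threshold = 0.001) {
  rows <- lapply(conditions, function(cond) {
    med <- build_condition(model, cond)
    if (inherits(med, "screen_exclusion"))
      return(data.frame(id = cond$id, source = cond$source, role = cond$role,
                        mode = cond$mode, mu = NA_real_,
                        status = med$reason, excluded = TRUE, grew = NA,
                        stringsAsFactors = FALSE))
    sol <- fba(model, medium = med)
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    data.frame(id = cond$id, source = cond$source, role = cond$role,
               mode = cond$mode, mu = mu, status = sol$status,
               excluded = FALSE, grew = call_growth(mu, threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary growth call from a predicted growth rate
#'
#' @param mu growth rate(s), 1/h; must be non-negative.
#' @param threshold strict threshold: a call is positive iff
#'   \code{mu > threshold}. The default 0.001 1/h is the value used to
#'   separate growth from numerical noise throughout the validation.
#' @return logical vector.
#' @export
call_growth <- function(mu, threshold = 0.001) {
  stopifnot(all(mu >= 0, na.rm = TRUE))
  mu > threshold
}

#' Confusion counts from paired predictions and observations
#'
#' @param predicted,actual logical vectors of equal length (TRUE = growth).
#' @return object of class \code{confusion_counts}: TP, FP, TN, FN.
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  keep <- !(is.na(predicted) | is.na(actual))
  p <- predicted[keep]; a <- actual[keep]
  out <- list(TP = sum(p & a), FP = sum(p & !a),
              TN = sum(!p & !a), FN = sum(!p & a))
  if (sum(unlist(out)) == 0L) stop("no complete prediction/observation pairs")
  structure(out, class = "confusion_counts")
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Statistical panel from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value and the Matthews correlation coefficient. Any 0/0 ratio
#' is undefined and reported as NA, never as 0. Percentages in the printed
#' summary are rounded half away from zero to integers.
#'
#' @param counts a \code{confusion_counts} (or list with TP/FP/TN/FN).
#' @return object of class \code{screen_stats} with the six statistics on
#'   the 0-1 (MCC: -1..1) scale, plus the counts.
#' @export
confusion_stats <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  stopifnot(n > 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  structure(list(counts = counts,
                 n = n,
                 accuracy = (TP + TN) / n,
                 sensitivity = ratio(TP, TP + FN),
                 specificity = ratio(TN, TN + FP),
                 ppv = ratio(TP, TP + FP),
                 npv = ratio(TN, TN + FN),
                 mcc = if (mcc_den == 0) NA_real_ else
                   (TP * TN - FP * FN) / mcc_den),
            class = "screen_stats")
}

#' @export
print.screen_stats <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else
    paste0(.round_half_away(100 * v), "%")
  with(x, cat("<screen_stats> n=", n,
              " (TP=", counts$TP, " FP=", counts$FP,
              " TN=", counts$TN, " FN=", counts$FN, ")\n",
              "  accuracy ", pct(accuracy),
              "  sensitivity ", pct(sensitivity),
              "  specificity ", pct(specificity), "\n",
              "  PPV ", pct(ppv), "  NPV ", pct(npv),
              "  MCC ", if (is.na(mcc)) "NA" else format(mcc, digits = 3),
              "\n", sep = ""))
  invisible(x)
}

#' Per-pair percent error and accuracy of growth-rate predictions
#'
#' For each pair, percent error = |pred - exp| / exp x 100 and accuracy =
#' 100 - percent error. Pairs with a zero experimental value are excluded
#' with a flag (percent error is undefined there).
#'
#' @param predicted,experimental numeric vectors of paired growth rates.
#' @param labels optional pair labels.
#' @return data.frame (\code{label}, \code{experimental}, \code{predicted},
#'   \code{percent_error}, \code{accuracy}, \code{excluded}) with the mean
#'   accuracy over included pairs in attribute \code{"mean_accuracy"} and
#'   mean percent error in \code{"mean_percent_error"}.
#' @export
growth_rate_accuracy <- function(predicted, experimental, labels = NULL) {
  stopifnot(length(predicted) == length(experimental))
  if (is.null(labels)) labels <- as.character(seq_along(predicted))
  excluded <- experimental == 0
  pe <- ifelse(excluded, NA_real_,
               abs(predicted - experimental) / experimental * 100)
  out <- data.frame(label = labels, experimental = experimental,
                    predicted = predicted, percent_error = pe,
                    accuracy = 100 - pe, excluded = excluded,
                    stringsAsFactors = FALSE)
  attr(out, "mean_accuracy") <- mean(out$accuracy[!excluded])
  attr(out, "mean_percent_error") <- mean(out$percent_error[!excluded])
  out
}

#' Read a plate layout / experimental calls pair
#'
#' Plate layout CSV: columns \code{well}, \code{source_metabolite_id},
#' \code{role}, \code{plate_id}. Calls CSV: \code{well}, \code{grew} (0/1).
#'
#' @param plate_path,calls_path CSV paths.
#' @return merged data.frame keyed by well.
#' @export
read_plate <- function(plate_path, calls_path = NULL) {
  plate <- utils::read.csv(plate_path, stringsAsFactors = FALSE)
  need <- c("well", "source_metabolite_id", "role")
  missing <- setdiff(need, names(plate))
  if (length(missing)) stop("plate layout lacks columns: ",
                            paste(missing, collapse = ", "))
  if (!is.null(calls_path)) {
    calls <- utils::read.csv(calls_path, stringsAsFactors = FALSE)
    plate <- merge(plate, calls[, c("well", "grew")], by = "well",
                   all.x = TRUE, sort = TRUE)
  }
  plate
}

#' Screen a plate layout against a model
#'
#' Builds one [screen_condition()] per well and runs the screen; when
#' experimental calls are attached, confusion statistics against them are
#' returned as well.
#'
#' @param model a \code{metabolic_model}.
#' @param plate data.frame from [read_plate()] (optionally with a
#'   \code{grew} column of experimental calls).
#' @param mode nitrogen regime for the simulation.
#' @param uptake per-source uptake bound.
#' @return list with \code{results} (per-well data.frame) and, when calls
#'   are present, \code{stats} (a \code{screen_stats}).
#' @export
screen_plate <- function(model, plate, mode = "non-diazotrophic",
                         uptake = 10) {
  conds <- lapply(seq_len(nrow(plate)), function(i)
    screen_condition(plate$source_metabolite_id[i], role = plate$role[i],
                     mode = mode, uptake = uptake, id = plate$well[i]))
  res <- run_screen(model, conds)
  res <- merge(plate, res[, c("id", "mu", "status", "excluded", "grew")],
               by.x = "well", by.y = "id", sort = TRUE)
  names(res)[names(res) == "grew.x"] <- "grew_observed"
  names(res)[names(res) == "grew.y"] <- "grew_predicted"
  out <- list(results = res)
  if ("grew_observed" %in% names(res)) {
    keep <- !res$excluded
    out$stats <- confusion_stats(confusion_counts(
      res$grew_predicted[keep], as.logical(res$grew_observed[keep])))
  }
  out
}
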