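# Classification of differentially expressed probes into three-point
# expression-trajectory patterns: late (change only after the intermediate
# stage), early (change completed by the intermediate stage), progressive
# (stepwise change across both transitions), or other.

.TRAJ_CLASSES <- c("late_up", "late_down", "progressive_up",
                   "progressive_down", "early", "other")

#' Classify stage contrasts into trajectory patterns
#'
#' Applies three-point pattern rules to probes that passed the
#' differential-expression filter, in fixed precedence:
#' \enumerate{
#'   \item \strong{late}: no significant early-to-intermediate change
#'     (\code{p_IE > alpha}) but a significant intermediate-to-late change
#'     (\code{p_IL <= alpha}); direction from the sign of \code{fc_LE}.
#'   \item \strong{early}: the intermediate-vs-early ratio sits within
#'     \code{earlyWindow} of the late-vs-early ratio on the signed
#'     fold-change scale (inclusive), with matching signs and a significant
#'     early leg (\code{p_IE <= alpha}) — the change is complete by the
#'     intermediate stage.
#'   \item \strong{progressive}: both legs significant with consistent
#'     direction across \code{fc_IE}, \code{fc_IL} and \code{fc_LE}.
#'   \item \strong{other}: none of the above.
#' }
#' Printed result tables often carry only the two early-referenced
#' contrasts; when \code{fc_IL}/\code{p_IL} are absent or \code{NA}, the
#' late-vs-early significance and sign stand in for the
#' intermediate-to-late leg. The window comparison uses a small numeric
#' tolerance so ratios equal at printed precision are inside the window.
#'
#' @param contrasts data.frame with columns \code{fc_IE}, \code{p_IE},
#'   \code{fc_LE}, \code{p_LE} and optionally \code{fc_IL}, \code{p_IL}
#'   and \code{probe_id}; rows must satisfy the DE filter.
#' @param alpha significance level for the per-leg tests (default 0.05).
#' @param earlyWindow maximum |fc_IE - fc_LE| on the signed fold-change
#'   scale for an early call (default 0.4).
#' @param checkDe verify rows pass the fold/p (and, when the column is
#'   present, intensity) filter before classifying (default TRUE).
#' @param foldThreshold,deAlpha,intensityFloor filter settings used for the
#'   \code{checkDe} verification.
#' @return data.frame of the input plus a \code{class} factor with levels
#'   \code{late_up}, \code{late_down}, \code{progressive_up},
#'   \code{progressive_down}, \code{early}, \code{other}.
#' @examples
#' rows <- data.frame(fc_IE = c(-2.1, 1.05), p_IE = c(0.0331, 0.8),
#'                    fc_LE = c(-2.1, 3.0), p_LE = c(0.0331, 0.01))
#' classifyContrasts(rows)$class
#' @export
classifyContrasts <- function(contrasts, alpha = 0.05, earlyWindow = 0.4,
                              checkDe = TRUE, foldThreshold = 2,
                              deAlpha = 0.05, intensityFloor = 500) {
  stopifnot(alpha > 0, alpha <= 1, earlyWindow >= 0)
  contrasts <- as.data.frame(contrasts)
  need <- c("fc_IE", "p_IE", "fc_LE", "p_LE")
  if (!all(need %in% colnames(contrasts)))
    stop("contrasts need columns: ", paste(need, collapse = ", "))
  if (checkDe && nrow(contrasts)) {
    notDe <- abs(contrasts$fc_LE) < foldThreshold |
      contrasts$p_LE > deAlpha
    if ("max_intensity" %in% colnames(contrasts))
      notDe <- notDe | contrasts$max_intensity <= intensityFloor
    if (any(notDe))
      stop("classify only filtered probes (",
           sum(notDe), " row(s) fail the DE filter)")
  }
  pIL <- if ("p_IL" %in% colnames(contrasts)) contrasts$p_IL
         else rep(NA_real_, nrow(contrasts))
  sIL <- if ("fc_IL" %in% colnames(contrasts)) sign(contrasts$fc_IL)
         else rep(NA_real_, nrow(contrasts))
  # fall back to the late-vs-early leg when the I->L contrast is absent
  pIL <- ifelse(is.na(pIL), contrasts$p_LE, pIL)
  sIL <- ifelse(is.na(sIL), sign(contrasts$fc_LE), sIL)
  tol <- 1e-9
  sLE <- sign(contrasts$fc_LE)
  sIE <- sign(contrasts$fc_IE)
  isLate <- contrasts$p_IE > alpha & pIL <= alpha
  isEarly <- abs(contrasts$fc_IE - contrasts$fc_LE) <= earlyWindow + tol &
    sIE == sLE & contrasts$p_IE <= alpha
  isProg <- contrasts$p_IE <= alpha & pIL <= alpha &
    sIE == sIL & sIL == sLE
  cls <- rep("other", nrow(contrasts))
  cls[isProg] <- ifelse(sLE[isProg] > 0, "progressive_up",
                        "progressive_down")
  cls[isEarly] <- "early"
  cls[isLate] <- ifelse(sLE[isLate] > 0, "late_up", "late_down")
  contrasts$class <- factor(cls, levels = .TRAJ_CLASSES)
  contrasts
}

#' Classify a DE partition into trajectory patterns
#'
#' Convenience wrapper: classifies the retained (up and down) probes of a
#' \code{DEPartition} with the filter settings it was built with.
#'
#' @param de a \code{DEPartition} from \code{\link{deFilter}}.
#' @inheritParams classifyContrasts
#' @return As \code{\link{classifyContrasts}}.
#' @export
classifyTrajectory <- function(de, alpha = 0.05, earlyWindow = 0.4) {
  stopifnot(inherits(de, "DEPartition"))
  classifyContrasts(rbind(de$up, de$down), alpha = alpha,
                    earlyWindow = earlyWindow, checkDe = TRUE,
                    foldThreshold = de$foldThreshold, deAlpha = de$alpha,
                    intensityFloor = de$intensityFloor)
}

#' Summarize trajectory-class counts and fractions
#'
#' Counts calls per pattern group (directions pooled) and expresses each as
#' a percentage of all classified (differentially expressed) probes,
#' rendered to one decimal.
#'
#' @param calls data.frame with a \code{class} column as produced by
#'   \code{\link{classifyContrasts}}.
#' @return data.frame with columns \code{class} (\code{late},
#'   \code{progressive}, \code{early}, \code{other}), \code{count} and
#'   \code{percent}.
#' @export
summarizeTrajectory <- function(calls) {
  groups <- c(late_up = "late", late_down = "late",
              progressive_up = "progressive",
              progressive_down = "progressive",
              early = "early", other = "other")
  lev <- c("late", "progressive", "early", "other")
  if (!nrow(calls))
    return(data.frame(class = lev, count = 0L, percent = 0))
  grp <- factor(groups[as.character(calls$class)], levels = lev)
  count <- as.integer(table(grp))
  data.frame(class = lev, count = count,
             percent = round(100 * count / sum(count), 1))
}
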