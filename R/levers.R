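## Static mechanical-advantage (MA) lever models of the forelimb.
##
## All three models express MA as 100 * r / R, the percentage ratio of the
## muscle force arm r to the resistance arm R, measured as straight-line
## distances from the joint rotation axis on dry-bone material. They are
## static osteological approximations: no ground-reaction-force vectors,
## joint angles through time, or sesamoid (pisiform) moment arms.

#' Estimate humeral length from a conspecific ulna/humerus ratio
#'
#' For specimens lacking a complete humerus, total humeral length can be
#' inferred from the ulna by applying the ulna/humerus ratio observed in a
#' conspecific individual preserving both elements. The reference ratio is
#' rounded before division (2 decimals by default), matching the convention
#' of reporting the conspecific ratio as a 2-decimal figure.
#'
#' @param ul_target ulna length (cm) of the specimen whose humerus is missing
#' @param ul_ref,hl_ref ulna and humerus lengths (cm) of the reference
#'   conspecific specimen
#' @param ratio_decimals decimals to which the reference ratio is rounded
#'   before use; `0` disables rounding
#' @return Estimated humeral length in cm, with attributes `estimated = TRUE`
#'   and `ratio` (the rounded ratio actually used).
#' @examples
#' estimate_humerus_length(16.26, 23.2, 19.53)  # 13.66 cm via ratio 1.19
#' @export
estimate_humerus_length <- function(ul_target, ul_ref, hl_ref,
                                    ratio_decimals = 2) {
  if (any(c(ul_target, ul_ref, hl_ref) <= 0) ||
      !all(is.finite(c(ul_target, ul_ref, hl_ref))))
    mfs_domain_error("all lengths must be positive and finite")
  if (ratio_decimals < 0) mfs_domain_error("ratio_decimals must be >= 0")
  ratio <- ul_ref / hl_ref
  if (ratio_decimals > 0) ratio <- round(ratio, ratio_decimals)
  structure(ul_target / ratio, estimated = TRUE, ratio = ratio)
}

#' Classical elbow mechanical advantage (index of fossorial ability)
#'
#' First-class lever centred on the elbow: force arm is the olecranon length
#' OL (triceps insertion lever), resistance arm the functional ulna length
#' `UL - OL` (joint axis to the distal tip of the ulna). Equivalent to the
#' index of fossorial ability, `MAe = 100 * OL / (UL - OL)`.
#'
#' @param ol olecranon length (cm)
#' @param ul total ulna length (cm); must exceed `ol`
#' @return MA as a percentage. Vectorized.
#' @examples
#' ma_elbow(2.6504, 16.26)  # ~19.47
#' @export
ma_elbow <- function(ol, ul) {
  check_lever(ol, ul, "OL", "UL")
  100 * ol / (ul - ol)
}

#' Elbow mechanical advantage with the manus in the lever chain
#'
#' Extends the classical elbow lever to the substrate contact point,
#' approximated by the distal tip of metacarpal III: the resistance arm
#' becomes the functional ulna length plus the manus segment `MTCIII_L`,
#' so `MA = 100 * OL / ((UL - OL) + MTCIII_L)` for a fully extended
#' (collinear) limb. An elbow/wrist chain angle below 180 degrees shortens
#' the effective resistance arm via the law of cosines.
#'
#' @inheritParams ma_elbow
#' @param mtciii_l manus segment length (cm), wrist joint line to the distal
#'   tip of metacarpal III; `0` collapses to [ma_elbow()]
#' @param chain_angle_deg angle (degrees) between the forearm and manus
#'   segments; default 180 (collinear, posture-free)
#' @return MA as a percentage; strictly below [ma_elbow()] whenever
#'   `mtciii_l > 0`.
#' @export
ma_elbow_manus <- function(ol, ul, mtciii_l, chain_angle_deg = 180) {
  check_lever(ol, ul, "OL", "UL")
  if (any(mtciii_l < 0)) mfs_domain_error("MTCIII_L must be >= 0")
  if (any(chain_angle_deg <= 0 | chain_angle_deg > 180))
    mfs_domain_error("chain_angle_deg must be in (0, 180]")
  ful <- ul - ol
  r_arm <- sqrt(ful^2 + mtciii_l^2 -
                  2 * ful * mtciii_l * cos(chain_angle_deg * pi / 180))
  100 * ol / r_arm
}

#' Wrist mechanical advantage
#'
#' Third-class lever with the rotation axis at the carpus: force arm is the
#' wrist-flexor arm WFA (wrist joint line to the proximal base of metacarpal
#' III), resistance arm the full manus segment `MTCIII_L`.
#' `MAw = 100 * WFA / MTCIII_L`.
#'
#' @param wfa wrist-flexor force arm (cm); must be below `mtciii_l`
#' @param mtciii_l manus segment length (cm)
#' @return MA as a percentage, in (0, 100).
#' @export
ma_wrist <- function(wfa, mtciii_l) {
  check_lever(wfa, mtciii_l, "WFA", "MTCIII_L")
  100 * wfa / mtciii_l
}

check_lever <- function(r, R, rname, Rname) {
  ok <- is.finite(r) & is.finite(R) & r > 0 & R > 0 & r < R
  if (!all(ok | (is.na(r) | is.na(R))))
    mfs_domain_error(sprintf("degenerate lever: need 0 < %s < %s", rname, Rname))
}

#' Mechanical-advantage profile for every specimen
#'
#' Computes the three lever models per specimen. Missing prerequisite
#' measurements yield missing entries with a warning naming the specimen;
#' `FUL` is derived as `UL - OL` where absent but needed.
#'
#' @param d a [mfs_data] dataset
#' @param chain_angle_deg passed to [ma_elbow_manus()]
#' @return data.frame with columns `specimen_id`, `group`, `MAe`,
#'   `MAe_MTCIII`, `MAw`, and `contains_estimate` (TRUE when any input
#'   measurement of that specimen is flagged as inferred).
#' @export
ma_profile <- function(d, chain_angle_deg = 180) {
  est <- estimated_fields(d)
  n <- nrow(d)
  out <- data.frame(specimen_id = d$specimen_id, group = d$group,
                    MAe = NA_real_, MAe_MTCIII = NA_real_, MAw = NA_real_,
                    contains_estimate = FALSE, stringsAsFactors = FALSE)
  skipped <- character()
  for (i in seq_len(n)) {
    ol <- d$OL[i]; ul <- d$UL[i]; m3 <- d$MTCIII_L[i]; wfa <- d$WFA[i]
    used <- character()
    if (!is.na(ol) && !is.na(ul)) {
      out$MAe[i] <- ma_elbow(ol, ul)
      used <- c(used, "OL", "UL")
      if (!is.na(m3)) {
        out$MAe_MTCIII[i] <- ma_elbow_manus(ol, ul, m3, chain_angle_deg)
        used <- c(used, "MTCIII_L")
      }
    }
    if (!is.na(wfa) && !is.na(m3)) {
      out$MAw[i] <- ma_wrist(wfa, m3)
      used <- c(used, "WFA", "MTCIII_L")
    }
    if (anyNA(out[i, c("MAe", "MAe_MTCIII", "MAw")]))
      skipped <- c(skipped, d$specimen_id[i])
    out$contains_estimate[i] <- length(intersect(est[[i]], used)) > 0
  }
  if (length(skipped))
    warning(sprintf("incomplete lever measurements, missing MA entries for: %s",
                    paste(unique(skipped), collapse = ", ")), call. = FALSE)
  out
}
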