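## Percentage functional indices of the forelimb.
##
## Each index is 100 * numerator / denominator over two linear measurements;
## the registry makes the convention explicit and overridable, since several
## denominator conventions circulate in the ecomorphological literature.

#' Functional index formula registry
#'
#' Returns the default formula map for the seven percentage indices:
#' robustness of the humerus shaft (HRI = HMLD/HL), epicondylar index
#' (EI = HEB/HL), olecranon index (OI = OL/UL), brachial indices of radius
#' and ulna (BIR = RL/HL, BIU = UL/HL), and shaft robustness of radius and
#' ulna relative to their own bone (RRI = RMLD/RL, URI = UMLD/UL).
#' `BIH` is accepted as an alias of `BIR` (both names appear in the
#' literature for the HL-denominated radial brachial index).
#'
#' @return Named list; each entry is `c(numerator, denominator)` in canonical
#'   measurement names.
#' @export
index_registry <- function() {
  list(HRI = c("HMLD", "HL"),
       EI  = c("HEB",  "HL"),
       OI  = c("OL",   "UL"),
       BIR = c("RL",   "HL"),
       BIH = c("RL",   "HL"),
       BIU = c("UL",   "HL"),
       RRI = c("RMLD", "RL"),
       URI = c("UMLD", "UL"))
}

#' Compute functional index profiles
#'
#' Evaluates the seven percentage indices for every specimen. Indices whose
#' numerator or denominator is missing are left missing; indices whose inputs
#' include an inferred measurement (e.g. an estimated humeral length) set
#' `contains_estimate`.
#'
#' @param d a [mfs_data] dataset
#' @param registry formula map as returned by [index_registry()]; replaceable
#'   to adopt an alternative denominator convention
#' @param indices names of indices to compute (default the canonical seven)
#' @return data.frame with `specimen_id`, `group`, one column per index
#'   (percent), and `contains_estimate`.
#' @examples
#' d <- mfs_data(data.frame(specimen_id = "h", taxon = "t", group = "digger",
#'                          UL = 16.26, HL = 13.66))
#' index_profile(d)$BIU  # 119.03
#' @export
index_profile <- function(d, registry = index_registry(),
                          indices = c("HRI", "EI", "OI", "BIR", "BIU",
                                      "RRI", "URI")) {
  unknown <- setdiff(indices, names(registry))
  if (length(unknown))
    mfs_schema_error(sprintf("unknown index name(s): %s",
                             paste(unknown, collapse = ", ")))
  est <- estimated_fields(d)
  out <- data.frame(specimen_id = d$specimen_id, group = d$group,
                    stringsAsFactors = FALSE)
  uses_est <- rep(FALSE, nrow(d))
  for (idx in indices) {
    f <- registry[[idx]]
    num <- d[[f[1]]]; den <- d[[f[2]]]
    bad <- !is.na(den) & den <= 0
    if (any(bad))
      mfs_domain_error(sprintf("specimen %s: %s denominator %s must be > 0",
                               d$specimen_id[bad][1], idx, f[2]))
    out[[idx]] <- 100 * num / den
    for (i in seq_len(nrow(d)))
      if (!is.na(out[[idx]][i]) && length(intersect(est[[i]], f)))
        uses_est[i] <- TRUE
  }
  out$contains_estimate <- uses_est
  out
}

#' Derive the functional ulna length
#'
#' Fills `FUL = UL - OL` (the resistance arm of the classical elbow lever)
#' wherever it is absent but both `UL` and `OL` are present. If a stored FUL
#' disagrees with `UL - OL` by more than 1% of UL a warning is raised (the
#' dataset validator rejects such tables outright at construction).
#'
#' @param d a [mfs_data] dataset
#' @return The dataset with FUL completed.
#' @export
derive_ful <- function(d) {
  have <- !is.na(d$UL) & !is.na(d$OL)
  if (any(have & d$OL >= d$UL))
    mfs_domain_error("OL >= UL: functional ulna length undefined")
  fill <- have & is.na(d$FUL)
  d$FUL[fill] <- d$UL[fill] - d$OL[fill]
  off <- have & !is.na(d$FUL) & abs(d$FUL - (d$UL - d$OL)) > 0.01 * d$UL
  if (any(off))
    warning(sprintf("FUL inconsistent with UL - OL for: %s",
                    paste(d$specimen_id[off], collapse = ", ")), call. = FALSE)
  d
}

#' Full functional-variable table (indices + lever models)
#'
#' Convenience composition of [index_profile()] and [ma_profile()]: the ten
#' functional variables used by the functional morphospace and the habit
#' comparison.
#'
#' @inheritParams ma_profile
#' @param registry passed to [index_profile()]
#' @return data.frame with `specimen_id`, `group`, the seven indices, the
#'   three MA models, and `contains_estimate`.
#' @export
functional_table <- function(d, registry = index_registry(),
                             chain_angle_deg = 180) {
  idx <- index_profile(d, registry)
  ma <- ma_profile(d, chain_angle_deg)
  out <- cbind(idx[, setdiff(names(idx), "contains_estimate")],
               ma[, c("MAe", "MAe_MTCIII", "MAw")])
  out$contains_estimate <- idx$contains_estimate | ma$contains_estimate
  out
}
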