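#' Toxin-neutralization ratio from OD600 growth data
#'
#' Degree of accessory-toxin neutralization by the full retron operon:
#' the full-operon OD600 ratio (induced/uninduced) divided by the
#' accessory-only OD600 ratio (induced/uninduced). A value of 1 means the
#' full operon grows no better, relative to its uninduced control, than the
#' accessory alone; values above 1 quantify rescue of accessory toxicity.
#'
#' @param od_full_ind,od_full_unind induced/uninduced OD600 of the
#'   full-operon strain.
#' @param od_acc_ind,od_acc_unind induced/uninduced OD600 of the
#'   accessory-only strain.
#' @return the neutralization ratio (positive real). Invariant to rescaling
#'   every OD by a common factor.
#' @examples
#' neutralization_ratio(0.9, 1.0, 0.09, 1.0)  # 10
#' @export
neutralization_ratio <- function(od_full_ind, od_full_unind,
                                 od_acc_ind, od_acc_unind) {
  vals <- c(od_full_ind, od_full_unind, od_acc_ind, od_acc_unind)
  if (any(vals < 0)) stop_validation("OD600 values must be non-negative")
  if (od_full_unind <= 0 || od_acc_unind <= 0 || od_acc_ind <= 0)
    stop_validation(
      "undefined ratio: uninduced ODs and accessory induced OD must be > 0")
  (od_full_ind / od_full_unind) / (od_acc_ind / od_acc_unind)
}

#' Plaque-forming units per mL of lysate
#'
#' @param plaque_count plaques counted on the plate.
#' @param lysate_volume_ul lysate volume plated, in microliters.
#' @param dilution_factor dilution of the lysate plated (e.g. 1e-6).
#' @return PFU per mL of the undiluted lysate.
#' @examples
#' pfu_per_ml(45, 45, 1e-6)  # 1e9
#' @export
pfu_per_ml <- function(plaque_count, lysate_volume_ul, dilution_factor) {
  if (any(lysate_volume_ul <= 0)) stop_validation("lysate volume must be > 0")
  if (any(dilution_factor <= 0)) stop_validation("dilution factor must be > 0")
  if (any(plaque_count < 0)) stop_validation("plaque counts must be >= 0")
  plaque_count / (lysate_volume_ul / 1000 * dilution_factor)
}

#' Phage sensitivity of a retron-defended strain
#'
#' Ratio of plaque-forming units on the full-operon strain to PFU on the
#' ncRNA/RT-only control. 1 indicates no retron-based defense, 0 total
#' defense; values above 1 (more plaques with the full operon) are reported
#' as-is.
#'
#' @param pfu_full_operon PFU/mL on the full-operon strain.
#' @param pfu_ncrna_rt PFU/mL on the ncRNA/RT control strain (> 0).
#' @return non-negative sensitivity ratio.
#' @export
sensitivity <- function(pfu_full_operon, pfu_ncrna_rt) {
  if (any(pfu_ncrna_rt <= 0))
    stop_validation("undefined sensitivity: control PFU must be > 0")
  if (any(pfu_full_operon < 0)) stop_validation("PFU must be >= 0")
  pfu_full_operon / pfu_ncrna_rt
}

#' Per-replicate neutralization ratios from a tidy OD table
#'
#' Metrics are computed within each biological replicate (paired by the
#' `replicate` key) and summarised as mean +/- SD, avoiding ratio-of-means
#' bias from pooling before the ratio.
#'
#' @param od data.frame with columns `strain`, `construct`
#'   ("full-operon"/"accessory-only"), `induced` (logical), `replicate`,
#'   `od600`.
#' @return data.frame: one row per strain x replicate with the
#'   neutralization ratio, plus attribute `summary` (per-strain mean, sd,
#'   n).
#' @export
neutralization_table <- function(od) {
  need <- c("strain", "construct", "induced", "replicate", "od600")
  miss <- setdiff(need, names(od))
  if (length(miss))
    stop_validation(sprintf("OD table is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  rows <- list()
  for (strain in unique(od$strain)) {
    d <- od[od$strain == strain, ]
    for (rep_id in unique(d$replicate)) {
      r <- d[d$replicate == rep_id, ]
      get <- function(cons, ind) {
        v <- r$od600[r$construct == cons & r$induced == ind]
        if (length(v) != 1L)
          stop_validation(sprintf(
            "strain %s replicate %s: need exactly one od600 for %s/%s",
            strain, rep_id, cons, if (ind) "induced" else "uninduced"))
        v
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, replicate = rep_id,
        neutralization = neutralization_ratio(
          get("full-operon", TRUE), get("full-operon", FALSE),
          get("accessory-only", TRUE), get("accessory-only", FALSE)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  s <- do.call(rbind, lapply(split(out, out$strain), function(g) {
    data.frame(strain = g$strain[1], mean = mean(g$neutralization),
               sd = sd(g$neutralization), n = nrow(g))
  }))
  rownames(s) <- NULL
  attr(out, "summary") <- s
  out
}

#' Per-replicate phage sensitivity from a tidy plaque table
#'
#' @param plaques data.frame with columns `strain`, `construct`
#'   ("full-operon"/"ncrna-rt"), `phage`, `replicate`, `plaque_count`,
#'   `lysate_volume_ul`, `dilution_factor`.
#' @return data.frame: one row per strain x phage x replicate with
#'   `pfu_full`, `pfu_control` and `sensitivity`, plus attribute `summary`.
#' @export
sensitivity_table <- function(plaques) {
  need <- c("strain", "construct", "phage", "replicate", "plaque_count",
            "lysate_volume_ul", "dilution_factor")
  miss <- setdiff(need, names(plaques))
  if (length(miss))
    stop_validation(sprintf("plaque table is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  rows <- list()
  for (key in unique(paste(plaques$strain, plaques$phage, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- plaques[plaques$strain == parts[1] & plaques$phage == parts[2], ]
    for (rep_id in unique(d$replicate)) {
      r <- d[d$replicate == rep_id, ]
      get <- function(cons) {
        v <- r[r$construct == cons, ]
        if (nrow(v) != 1L)
          stop_validation(sprintf(
            "strain %s phage %s replicate %s: need exactly one row for %s",
            parts[1], parts[2], rep_id, cons))
        pfu_per_ml(v$plaque_count, v$lysate_volume_ul, v$dilution_factor)
      }
      pfu_full <- get("full-operon")
      pfu_ctrl <- get("ncrna-rt")
      rows[[length(rows) + 1L]] <- data.frame(
        strain = parts[1], phage = parts[2], replicate = rep_id,
        pfu_full = pfu_full, pfu_control = pfu_ctrl,
        sensitivity = sensitivity(pfu_full, pfu_ctrl),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  s <- do.call(rbind, lapply(split(out, paste(out$strain, out$phage)),
                             function(g) {
    data.frame(strain = g$strain[1], phage = g$phage[1],
               mean = mean(g$sensitivity), sd = sd(g$sensitivity),
               n = nrow(g))
  }))
  rownames(s) <- NULL
  attr(out, "summary") <- s
  out
}
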