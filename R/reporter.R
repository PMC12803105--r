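#' Sequential dual-luciferase normalization
#'
#' Per well the firefly/renilla ratio is formed; per (construct, condition,
#' biological replicate) the median over technical replicates is taken
#' (biological replicates are the test units). The median is then divided
#' by the control-construct median of the same condition and biological
#' replicate, and, when \code{withEffectorNorm = TRUE}, the effector value
#' is further divided by the control-effector value of the same construct
#' and replicate. The result is reported as log2, so values significantly
#' below 0 indicate repression by the effector. The whole chain is
#' multiplicative: rescaling all firefly readings of one biological
#' replicate by any constant cancels exactly.
#'
#' @param wells data.frame with columns construct_id, condition (effector /
#'   control_effector), bio_rep, tech_rep, firefly, renilla (> 0).
#' @param controlConstruct id of the control-3'UTR construct.
#' @param withEffectorNorm divide by the control-effector value (step 3);
#'   \code{FALSE} reproduces the variant without that normalization.
#' @return data.frame: construct_id, bio_rep, log2_activity (one row per
#'   construct and biological replicate, effector condition).
#' @export
normalizeLuciferase <- function(wells, controlConstruct,
                                withEffectorNorm = TRUE) {
  need <- c("construct_id", "condition", "bio_rep", "tech_rep",
            "firefly", "renilla")
  if (!all(need %in% names(wells)))
    stop("wells must have columns ", paste(need, collapse = ", "))
  if (any(wells$renilla <= 0)) stop("non-positive renilla luminescence")
  if (any(wells$firefly <= 0)) stop("non-positive firefly luminescence")
  if (!controlConstruct %in% wells$construct_id)
    stop("control construct absent from wells")
  fr <- wells$firefly / wells$renilla
  key <- interaction(wells$construct_id, wells$condition, wells$bio_rep,
                     drop = TRUE)
  med <- tapply(fr, key, median)
  info <- do.call(rbind, strsplit(names(med), ".", fixed = TRUE))
  grp <- data.frame(construct_id = info[, 1L], condition = info[, 2L],
                    bio_rep = info[, 3L], fr = as.numeric(med))
  ctrlKey <- paste(grp$condition, grp$bio_rep)
  ctrl <- grp[grp$construct_id == controlConstruct, ]
  idx <- match(ctrlKey, paste(ctrl$condition, ctrl$bio_rep))
  if (anyNA(idx))
    stop("missing control-construct wells for some ",
         "(condition, biological replicate) pairs")
  grp$rel <- grp$fr / ctrl$fr[idx]
  eff <- grp[grp$condition == "effector", ]
  if (withEffectorNorm) {
    ce <- grp[grp$condition == "control_effector", ]
    idx <- match(paste(eff$construct_id, eff$bio_rep),
                 paste(ce$construct_id, ce$bio_rep))
    if (anyNA(idx))
      stop("missing control-effector wells for some ",
           "(construct, biological replicate) pairs")
    eff$rel <- eff$rel / ce$rel[idx]
  }
  out <- data.frame(construct_id = eff$construct_id,
                    bio_rep = eff$bio_rep,
                    log2_activity = log2(eff$rel))
  out[order(out$construct_id, out$bio_rep), , drop = FALSE]
}

#' One-sample t tests on normalized activities with BH adjustment
#'
#' Per construct a two-sided one-sample Student t test of mean
#' log2 activity against 0, Benjamini-Hochberg adjusted across the batch.
#' Constructs with zero variance get p = 1 with a warning flag; constructs
#' with fewer than two replicates are excluded with a warning.
#'
#' @param activities data.frame from [normalizeLuciferase()].
#' @return data.frame: construct_id, n, mean_log2, t_statistic, p, padj,
#'   flag ("" or "zero_variance").
#' @export
oneSampleTests <- function(activities) {
  sp <- split(activities$log2_activity, activities$construct_id)
  small <- names(sp)[lengths(sp) < 2L]
  if (length(small)) {
    warning("constructs excluded (n < 2): ", paste(small, collapse = ", "))
    sp <- sp[lengths(sp) >= 2L]
  }
  if (!length(sp)) stop("no construct with >= 2 replicates")
  rows <- lapply(names(sp), function(id) {
    x <- sp[[id]]
    if (sd(x) == 0) {
      warning("zero variance for construct ", id, "; p set to 1")
      return(data.frame(construct_id = id, n = length(x),
                        mean_log2 = mean(x), t_statistic = NA_real_,
                        p = 1, flag = "zero_variance"))
    }
    ht <- t.test(x, mu = 0)
    data.frame(construct_id = id, n = length(x), mean_log2 = mean(x),
               t_statistic = unname(ht$statistic), p = ht$p.value,
               flag = "")
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out[, c("construct_id", "n", "mean_log2", "t_statistic", "p", "padj",
          "flag")]
}

#' Chi-square test on defect proportions between two groups
#'
#' 2x2 Pearson chi-square (1 df) on defect/normal counts, sharing the
#' implementation of [overlapTest()].
#'
#' @param counts 2x2 matrix or table: rows = groups, columns =
#'   c(defect, normal).
#' @param correct apply Yates continuity correction.
#' @return list of class \code{clipContingency}.
#' @examples
#' proportionTest(rbind(injected = c(70, 30), control = c(5, 95)))
#' @export
proportionTest <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("counts must be a 2x2 matrix of defect/normal per group")
  chiSquare2x2(as.table(counts), correct = correct)
}

#' Paired eye/lens morphometry
#'
#' Per record the area is the product of the minor and major diameters;
#' per larva and side the lens-to-eye area ratio is formed. Across larvae,
#' two-sided paired Student t tests compare injected vs control sides for
#' eye area, lens area, the area ratio and (when present) cornea
#' thickness. Larvae missing one side for an endpoint are dropped from
#' that endpoint with a warning. Endpoints with all-zero paired
#' differences report p = 1 with a flag.
#'
#' @param measurements data.frame with columns larva_id, side (injected /
#'   control), structure (eye / lens), minor_diameter, major_diameter and
#'   optionally cornea_thickness (on eye rows).
#' @return list with \code{areas} (per larva/side/structure),
#'   \code{ratios} (per larva/side) and \code{tests} (data.frame endpoint,
#'   n, mean_injected, mean_control, t_statistic, p, flag).
#' @export
pairedMorphometry <- function(measurements) {
  m <- measurements
  stopifnot(all(c("larva_id", "side", "structure", "minor_diameter",
                  "major_diameter") %in% names(m)))
  if (any(m$minor_diameter <= 0 | m$major_diameter <= 0))
    stop("diameters must be positive")
  m$area <- m$minor_diameter * m$major_diameter
  wide <- function(values, rows) {
    ## larva x side matrix for one endpoint
    tapply(values[rows], list(m$larva_id[rows], m$side[rows]),
           function(v) v[1L])
  }
  eyeRows <- m$structure == "eye"
  lensRows <- m$structure == "lens"
  eye <- wide(m$area, eyeRows)
  lens <- wide(m$area, lensRows)
  ratio <- lens[rownames(eye), , drop = FALSE] / eye
  endpoints <- list(eye_area = eye, lens_area = lens,
                    lens_eye_ratio = ratio)
  if ("cornea_thickness" %in% names(m) &&
      any(!is.na(m$cornea_thickness)))
    endpoints$cornea_thickness <-
      wide(m$cornea_thickness, eyeRows & !is.na(m$cornea_thickness))
  tests <- lapply(names(endpoints), function(nm) {
    w <- endpoints[[nm]]
    ok <- stats::complete.cases(w)
    if (any(!ok))
      warning(sum(!ok), " unpaired larva(e) dropped for ", nm)
    w <- w[ok, , drop = FALSE]
    if (nrow(w) < 2L) stop("fewer than 2 paired larvae for ", nm)
    d <- w[, "injected"] - w[, "control"]
    if (sd(d) == 0) {
      flag <- "zero_variance"
      tStat <- NA_real_; p <- 1
      warning("zero paired variance for ", nm, "; p set to 1")
    } else {
      ht <- t.test(w[, "injected"], w[, "control"], paired = TRUE)
      tStat <- unname(ht$statistic); p <- ht$p.value; flag <- ""
    }
    data.frame(endpoint = nm, n = nrow(w),
               mean_injected = mean(w[, "injected"]),
               mean_control = mean(w[, "control"]),
               t_statistic = tStat, p = p, flag = flag)
  })
  ratioDf <- data.frame(
    larva_id = rep(rownames(ratio), ncol(ratio)),
    side = rep(colnames(ratio), each = nrow(ratio)),
    lens_eye_ratio = as.vector(ratio))
  list(areas = m[, c("larva_id", "side", "structure", "area")],
       ratios = ratioDf[!is.na(ratioDf$lens_eye_ratio), ],
       tests = do.call(rbind, tests))
}
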