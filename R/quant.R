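#' LUMIER fold-binding
#'
#' Ratio of luciferase activity in eluates and lysates, normalised
#' against the control pair (empty vector): fold(pair) =
#' (eluate/lysate)_pair / (eluate/lysate)_control.
#'
#' @param records data.frame with columns pair_id, eluate_lum,
#'   lysate_lum, is_control (exactly one control row).
#' @return Named numeric vector of fold-binding values per pair
#'   (the control maps to exactly 1).
#' @examples
#' recs <- data.frame(pair_id = c("ctrl", "a"),
#'                    eluate_lum = c(5, 20), lysate_lum = c(100, 100),
#'                    is_control = c(TRUE, FALSE))
#' lumier_fold_binding(recs)  # ctrl 1, a 4
#' @export
lumier_fold_binding <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("pair_id", "eluate_lum", "lysate_lum", "is_control") %in%
                  names(records)))
  if (any(records$eluate_lum <= 0) || any(records$lysate_lum <= 0))
    stop("all luminescence readings must be positive", call. = FALSE)
  if (sum(records$is_control) != 1L)
    stop(sprintf("need exactly one control record, found %d",
                 sum(records$is_control)), call. = FALSE)
  ratio <- records$eluate_lum / records$lysate_lum
  fold <- ratio / ratio[records$is_control]
  names(fold) <- records$pair_id
  fold
}

#' Dual-luciferase reporter fold-induction
#'
#' Per well, the firefly/renilla ratio; per condition, the mean ratio
#' divided by the mean control ratio. The sd is computed on the
#' per-replicate folds (each replicate ratio divided by the control
#' mean).
#'
#' @param records data.frame with columns condition, firefly, renilla,
#'   is_control, replicate.
#' @return data.frame with columns condition, fold, sd, n.
#' @export
reporter_fold_induction <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("condition", "firefly", "renilla", "is_control", "replicate")
                %in% names(records)))
  if (any(records$firefly <= 0) || any(records$renilla <= 0))
    stop("all luminescence readings must be positive", call. = FALSE)
  if (!any(records$is_control))
    stop("no control replicates present", call. = FALSE)
  records$ratio <- records$firefly / records$renilla
  ctrl_mean <- mean(records$ratio[records$is_control])
  conds <- unique(records$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    folds <- records$ratio[records$condition == cc] / ctrl_mean
    data.frame(condition = cc, fold = mean(folds),
               sd = if (length(folds) > 1L) stats::sd(folds) else 0,
               n = length(folds), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ChIP-qPCR fold-enrichment over IgG
#'
#' fold = efficiency^(control_ct - antibody_ct): the amount of
#' antibody-precipitated DNA relative to the IgG control, assuming a
#' shared amplification efficiency per cycle.
#'
#' @param antibody_ct qPCR cycle threshold of the specific antibody IP.
#' @param control_ct Cycle threshold of the IgG control IP.
#' @param efficiency Per-cycle amplification efficiency in (1, 2]
#'   (default 2, perfect doubling). Vectorised over all arguments.
#' @return Numeric fold-enrichment (1 when the Cts are equal).
#' @examples
#' chip_fold_enrichment(22, 25)       # 8
#' chip_fold_enrichment(23, 25, 1.9)  # 3.61
#' @export
chip_fold_enrichment <- function(antibody_ct, control_ct, efficiency = 2) {
  if (any(efficiency <= 1) || any(efficiency > 2))
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  efficiency^(control_ct - antibody_ct)
}

#' Read plate-level quantification records from TSV
#'
#' @param path TSV file whose columns mirror one of the record layouts
#'   (LUMIER: pair_id, eluate_lum, lysate_lum, is_control; reporter:
#'   condition, firefly, renilla, is_control, replicate; ChIP:
#'   target_region, antibody_ct, control_ct and optional efficiency).
#' @param mode One of "lumier", "reporter", "chip".
#' @return data.frame of validated records.
#' @export
read_plate_records <- function(path, mode = c("lumier", "reporter", "chip")) {
  mode <- match.arg(mode)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  needed <- switch(mode,
    lumier = c("pair_id", "eluate_lum", "lysate_lum", "is_control"),
    reporter = c("condition", "firefly", "renilla", "is_control", "replicate"),
    chip = c("target_region", "antibody_ct", "control_ct"))
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop(sprintf("plate file '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  if ("is_control" %in% names(tab)) tab$is_control <- as.logical(tab$is_control)
  tab
}
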