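#' Islet autoantibody positivity thresholds
#'
#' Fixed positivity cut-offs (U/ml) for the three islet autoantibody ELISA
#' assays, set at the 97.5th centile of 1500 controls: GAD >= 11,
#' IA2 >= 7.5, ZnT8 >= 65. Comparisons are inclusive.
#'
#' @param gad,ia2,znt8 Thresholds in U/ml; all strictly positive.
#' @return An object of class \code{antibody_thresholds}.
#' @export
antibody_thresholds <- function(gad = 11, ia2 = 7.5, znt8 = 65) {
  thr <- c(gad = gad, ia2 = ia2, znt8 = znt8)
  if (any(!is.finite(thr)) || any(thr <= 0)) {
    stop("antibody thresholds must be finite and strictly positive")
  }
  structure(as.list(thr), class = "antibody_thresholds")
}

.assays <- c("gad", "ia2", "znt8")

#' Classify antibody titres against positivity thresholds
#'
#' Each assay is called positive when its titre is greater than or equal to
#' the threshold. A subject with an absent (NA) titre is untested for that
#' assay (the positivity flag stays NA); a subject is \code{tested} when all
#' three titres are present, matching the convention that subjects with
#' failed assays are excluded from panel denominators.
#'
#' @param titres Data.frame with columns \code{subject_id}, \code{gad},
#'   \code{ia2}, \code{znt8} (titres in U/ml, NA = not tested).
#' @param thr An [antibody_thresholds] object.
#' @return A data.frame of panel calls: \code{subject_id}, \code{gad_pos},
#'   \code{ia2_pos}, \code{znt8_pos}, \code{n_pos} (NA for untested
#'   subjects), \code{tested}.
#' @export
classify_antibodies <- function(titres, thr = antibody_thresholds()) {
  stopifnot(inherits(thr, "antibody_thresholds"))
  need <- c("subject_id", .assays)
  missing_cols <- setdiff(need, names(titres))
  if (length(missing_cols) > 0L) {
    stop("titre table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (a in .assays) {
    v <- titres[[a]]
    if (any(v < 0, na.rm = TRUE)) stop("negative titre in assay ", a)
  }
  pos <- lapply(.assays, function(a) titres[[a]] >= thr[[a]])
  names(pos) <- paste0(.assays, "_pos")
  tested <- Reduce(`&`, lapply(.assays, function(a) !is.na(titres[[a]])))
  n_pos <- ifelse(tested,
                  pos$gad_pos + pos$ia2_pos + pos$znt8_pos,
                  NA_integer_)
  data.frame(subject_id = titres$subject_id,
             gad_pos = pos$gad_pos, ia2_pos = pos$ia2_pos,
             znt8_pos = pos$znt8_pos,
             n_pos = as.integer(n_pos), tested = tested,
             stringsAsFactors = FALSE)
}

#' Venn-cell counts of the three-antibody panel
#'
#' Partitions tested subjects by positivity pattern: single-positive cells
#' per assay, any-two, all-three, at-least-one and none. Only subjects with
#' all three assays tested are counted.
#'
#' @param calls Panel calls from [classify_antibodies()].
#' @return Named list of integer counts: \code{gad_only}, \code{ia2_only},
#'   \code{znt8_only}, \code{exactly_two}, \code{all_three},
#'   \code{at_least_one}, \code{none}, plus \code{n_tested}.
#' @export
venn_counts <- function(calls) {
  k <- calls[calls$tested, , drop = FALSE]
  g <- k$gad_pos; i <- k$ia2_pos; z <- k$znt8_pos
  n_pos <- g + i + z
  out <- list(
    gad_only = sum(g & n_pos == 1L),
    ia2_only = sum(i & n_pos == 1L),
    znt8_only = sum(z & n_pos == 1L),
    exactly_two = sum(n_pos == 2L),
    all_three = sum(n_pos == 3L),
    at_least_one = sum(n_pos >= 1L),
    none = sum(n_pos == 0L),
    n_tested = nrow(k))
  lapply(out, as.integer)
}

#' Incremental diagnostic yield of adding an assay to a base panel
#'
#' How many additional antibody-positive subjects an extra assay finds
#' beyond a base panel, and the positivity rate of the added assay among
#' base-panel-negative subjects (e.g. ZnT8 positivity among GAD/IA2-negative
#' children).
#'
#' @param calls Panel calls from [classify_antibodies()].
#' @param base_assays Character vector, subset of \code{c("gad","ia2","znt8")}.
#' @param added_assay Single assay not in \code{base_assays}.
#' @return List: \code{n_tested}, \code{n_base_pos} (positive on any base
#'   assay), \code{n_with_added} (positive on base or added),
#'   \code{n_added_only} (added-positive among base-negative), and
#'   \code{pct_added_among_base_negative} (percent; NA with
#'   \code{undefined_pct = TRUE} when no subject is base-negative).
#' @export
incremental_yield <- function(calls, base_assays = c("gad", "ia2"),
                              added_assay = "znt8") {
  base_assays <- match.arg(base_assays, .assays, several.ok = TRUE)
  added_assay <- match.arg(added_assay, .assays)
  if (added_assay %in% base_assays) stop("added_assay must not be in base_assays")
  k <- calls[calls$tested, , drop = FALSE]
  base_pos <- Reduce(`|`, lapply(base_assays, function(a) k[[paste0(a, "_pos")]]))
  added_pos <- k[[paste0(added_assay, "_pos")]]
  n_base_neg <- sum(!base_pos)
  n_added_only <- sum(added_pos & !base_pos)
  list(n_tested = nrow(k),
       n_base_pos = sum(base_pos),
       n_with_added = sum(base_pos | added_pos),
       n_added_only = n_added_only,
       pct_added_among_base_negative =
         if (n_base_neg == 0L) NA_real_ else 100 * n_added_only / n_base_neg,
       undefined_pct = n_base_neg == 0L)
}

#' Build a panel-call table realizing given Venn cells
#'
#' Constructs a deterministic set of panel calls with the requested number
#' of subjects in each positivity pattern. Useful for reproducing published
#' category counts when per-subject titres are not available.
#'
#' @param gad_only,ia2_only,znt8_only Single-positive counts.
#' @param gad_ia2,gad_znt8,ia2_znt8 Double-positive counts (exactly two).
#' @param all_three Triple-positive count.
#' @param none Count of tested, fully negative subjects.
#' @return A panel-call data.frame as from [classify_antibodies()].
#' @export
calls_from_venn <- function(gad_only = 0, ia2_only = 0, znt8_only = 0,
                            gad_ia2 = 0, gad_znt8 = 0, ia2_znt8 = 0,
                            all_three = 0, none = 0) {
  patt <- rbind(
    matrix(rep(c(TRUE, FALSE, FALSE), gad_only), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, TRUE, FALSE), ia2_only), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, TRUE), znt8_only), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, TRUE, FALSE), gad_ia2), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, FALSE, TRUE), gad_znt8), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, TRUE, TRUE), ia2_znt8), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, TRUE, TRUE), all_three), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, FALSE), none), ncol = 3, byrow = TRUE))
  n <- nrow(patt)
  data.frame(subject_id = sprintf("S%03d", seq_len(max(n, 0L))),
             gad_pos = patt[, 1], ia2_pos = patt[, 2], znt8_pos = patt[, 3],
             n_pos = as.integer(rowSums(patt)),
             tested = rep(TRUE, n),
             stringsAsFactors = FALSE)
}
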