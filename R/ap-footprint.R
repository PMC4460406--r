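#' Correct a raw 2-aminopurine intensity for buffer and protein background
#'
#' Steady-state 2-AP readings include buffer fluorescence and a protein
#' contribution measured on an unlabeled replication-fork substrate; both
#' are subtracted: \code{corrected = raw - blank - (control - blank)}.
#'
#' @param raw observed intensity, a.u. (>= 0).
#' @param buffer_blank buffer-only reading, a.u.
#' @param unlabeled_control protein + unlabeled-substrate reading, a.u.
#' @return Corrected intensity (vectorized). Non-positive corrected values
#'   are returned as \code{NA} with attribute \code{unusable = TRUE}: they
#'   carry no usable signal.
#' @examples
#' correct_intensity(120, 10, 25)  # 95
#' @export
correct_intensity <- function(raw, buffer_blank = 0, unlabeled_control = 0) {
  if (any(raw < 0)) stop("raw intensities must be non-negative")
  corrected <- raw - buffer_blank - (unlabeled_control - buffer_blank)
  bad <- corrected <= 0
  if (any(bad)) {
    corrected[bad] <- NA_real_
    attr(corrected, "unusable") <- TRUE
  }
  corrected
}

#' Fold change of 2-AP intensity on protein binding
#'
#' Ratio of the protein-bound corrected intensity to the DNA-only corrected
#' intensity, with first-order error propagation:
#' \code{sd(ratio) = ratio * sqrt((sa/a)^2 + (sb/b)^2)}.
#'
#' @param with_protein corrected intensity with enzyme, a.u. (> 0).
#' @param dna_only corrected DNA-only intensity, a.u. (> 0).
#' @param sd_with,sd_dna standard deviations of the two intensities.
#' @return List with \code{fold} and \code{sd}.
#' @examples
#' fold_change(200, 100, 10, 5)
#' @export
fold_change <- function(with_protein, dna_only, sd_with = 0, sd_dna = 0) {
  if (any(!is.finite(with_protein)) || any(with_protein <= 0) ||
      any(!is.finite(dna_only)) || any(dna_only <= 0))
    stop("intensities must be finite and positive")
  fold <- with_protein / dna_only
  sd <- fold * sqrt((sd_with / with_protein)^2 + (sd_dna / dna_only)^2)
  list(fold = fold, sd = sd)
}

#' Classify a fold change as increase, decrease or none
#'
#' Quantizes a qualitative fluorescence response with two gates: an effect
#' size gate (\code{fold >= 1 + delta} for an increase,
#' \code{fold <= 1/(1 + delta)} for a decrease) and a significance gate
#' (\code{|fold - 1| >= z * sd}). Both must pass; otherwise the call is
#' \code{"none"}.
#'
#' @param fold fold change (> 0), vectorized.
#' @param sd propagated standard deviation of the fold.
#' @param delta minimal relative effect size (default 0.2).
#' @param z significance multiplier on the propagated sd (default 2).
#' @return Character vector in \code{c("increase", "none", "decrease")}.
#' @export
classify_response <- function(fold, sd = 0, delta = 0.2, z = 2) {
  if (any(fold <= 0)) stop("fold changes must be positive")
  stopifnot(delta >= 0, z >= 0)
  up <- fold >= 1 + delta & (fold - 1) >= z * sd
  dn <- fold <= 1 / (1 + delta) & (1 - fold) >= z * sd
  ifelse(up, "increase", ifelse(dn, "decrease", "none"))
}

# per-construct fold changes of a panel for one condition vs DNA-only
.panel_folds <- function(panel, condition) {
  dna <- panel[panel$condition == "DNA", ]
  sel <- panel[panel$condition == condition, ]
  if (nrow(sel) == 0)
    stop("condition '", condition, "' not present in panel; available: ",
         paste(unique(panel$condition), collapse = ", "))
  i <- match(sel$construct_id, dna$construct_id)
  if (anyNA(i))
    stop("construct(s) without a DNA-only reference row: ",
         paste(sel$construct_id[is.na(i)], collapse = ", "))
  fc <- fold_change(sel$intensity, dna$intensity[i],
                    sel$intensity_sd, dna$intensity_sd[i])
  data.frame(construct_id = sel$construct_id,
             probe_position = sel$probe_position, strand = sel$strand,
             context = sel$context, gap_nt = sel$gap_nt,
             fold = fc$fold, fold_sd = fc$sd)
}

#' Infer an enzyme footprint from a 2-AP panel
#'
#' Turns per-construct fold changes under one enzyme condition into a
#' base-pair-resolution footprint. Lagging-strand probes report melting:
#' the melted count is the maximal run of junction-proximal positions
#' (N+1, N+2, ...) called \code{"increase"}, subject to the attribution
#' rule that an increase at an internally probed position N+k is attributed
#' to unstacking of the already-melted N+(k-1) base -- not to melting at
#' N+k -- whenever the same position probed at the junction shows no
#' increase. When an internal increase at a position beyond the current run
#' has no junction-context probe to disambiguate it, the result carries
#' status \code{"ambiguous attribution"} instead of a count. Leading-strand
#' probes report enzyme contact with the downstream template: any response
#' (increase or decrease) is contact evidence, and the contacted count is
#' the contiguous span bounded by the outermost responding positions -- a
#' silent probe flanked by responding ones sits inside the binding pocket.
#'
#' @param panel an \code{ap_panel} (from \code{\link{simulate_ap_panel}} or
#'   \code{\link{read_ap_panel}}).
#' @param condition condition label to analyze, e.g. \code{"+DNAP"}.
#' @param delta,z classification thresholds passed to
#'   \code{\link{classify_response}}.
#' @return Object of class \code{"footprint_result"}: \code{melted_bp},
#'   \code{contacted_template_bases}, the per-position call table with
#'   attribution notes, and \code{status} (\code{"ok"} or
#'   \code{"ambiguous attribution"}).
#' @examples
#' panel <- simulate_ap_panel(ap_pattern_dnap(noise = 0), seed = 1)
#' infer_footprint(panel, "+DNAP")  # melted 2, contacted 3
#' @export
infer_footprint <- function(panel, condition, delta = 0.2, z = 2) {
  folds <- .panel_folds(panel, condition)
  folds$call <- classify_response(folds$fold, folds$fold_sd, delta, z)
  folds$note <- ""

  lag <- folds[folds$strand == "lagging", ]
  status <- "ok"
  melted <- 0L
  if (nrow(lag) > 0) {
    # Walk the reference fork (smallest gap present) outward from the
    # junction: base pair k of that fork is probe position g0 + ... the
    # k-th paired position, i.e. absolute position g0 + k. Junction-context
    # probes from forks of other gaps disambiguate, by absolute position,
    # whether an internal-probe increase reflects melting at that position
    # or unstacking of the already-melted neighbour.
    g0 <- min(lag$gap_nt)
    fork <- lag[lag$gap_nt == g0, ]
    for (k in seq_len(max(fork$probe_position - g0))) {
      if (k != melted + 1L) break
      at_k <- fork[fork$probe_position - g0 == k, ]
      if (nrow(at_k) == 0 || all(at_k$call != "increase")) break
      if (any(at_k$context == "junction" & at_k$call == "increase")) {
        melted <- k
        next
      }
      # increase seen only on an internal-context probe: consult junction
      # probes at the same absolute position (other fork geometries)
      pos <- g0 + k
      junc <- lag[lag$context == "junction" & lag$probe_position == pos, ]
      if (nrow(junc) == 0) {
        status <- "ambiguous attribution"
        break
      }
      if (all(junc$call != "increase")) {
        # no melting when this position is the junction base pair: the
        # internal increase is unstacking of the melted neighbour
        folds$note[folds$strand == "lagging" &
                     folds$probe_position == pos &
                     folds$context == "internal"] <-
          sprintf("attributed to unstacking at N+%d", pos - 1L)
        break
      }
      melted <- k
    }
  }

  # leading strand: contact footprint is the contiguous span bounded by the
  # outermost responding positions (increase or decrease); a silent probe
  # flanked by responding ones lies inside the binding pocket and counts
  lead <- folds[folds$strand == "leading", ]
  resp <- lead$probe_position[lead$call != "none"]
  contacted <- if (length(resp) == 0) 0L
  else as.integer(max(resp) - min(resp) + 1L)

  structure(list(
    melted_bp = if (status == "ok") melted else NA_integer_,
    contacted_template_bases = contacted,
    calls = folds, condition = condition,
    thresholds = c(delta = delta, z = z),
    status = status),
    class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("2-AP footprint, condition %s (%s)\n", x$condition, x$status))
  if (x$status == "ok")
    cat(sprintf("  melted base pairs: %d\n", x$melted_bp))
  cat(sprintf("  contacted template bases (leading strand): %d\n",
              x$contacted_template_bases))
  print(x$calls[, c("probe_position", "strand", "context", "gap_nt",
                    "fold", "call", "note")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Test for synergistic base-pair melting by two enzymes
#'
#' Synergy is declared on excess-over-baseline fold changes
#' \code{dF = fold - 1}: the combined-enzyme excess must exceed the sum of
#' the single-enzyme excesses by more than \code{z} times the propagated
#' error, \code{dF_AB > dF_A + dF_B + z * sqrt(sd_A^2 + sd_B^2 + sd_AB^2)}.
#' Mere additivity is not synergy. Symmetric in A and B.
#'
#' @param fold_A,fold_B,fold_AB fold changes for enzyme A alone, enzyme B
#'   alone, and both together (> 0).
#' @param sd_A,sd_B,sd_AB their propagated standard deviations.
#' @param z error multiplier (default 2).
#' @return List with \code{synergy} (logical) and \code{margin}
#'   (\code{dF_AB - dF_A - dF_B - z*sd}, positive when synergistic).
#' @export
detect_synergy <- function(fold_A, fold_B, fold_AB,
                           sd_A = 0, sd_B = 0, sd_AB = 0, z = 2) {
  stopifnot(fold_A > 0, fold_B > 0, fold_AB > 0, z >= 0)
  excess <- (fold_AB - 1) - (fold_A - 1) - (fold_B - 1)
  margin <- excess - z * sqrt(sd_A^2 + sd_B^2 + sd_AB^2)
  list(synergy = margin > 0, margin = margin)
}

#' Largest primer-end-to-junction gap with synergistic melting
#'
#' Applies \code{\link{detect_synergy}} to the junction-base-pair probe of
#' the panel at each gap, using the fold changes of the two single-enzyme
#' conditions and the combined condition. Synergy is expected to be
#' contiguous in the gap (if the enzymes cooperate across a gap g they
#' cooperate across any smaller gap); a non-contiguous pattern is flagged.
#'
#' @param panels named list of \code{ap_panel} objects keyed by gap
#'   (\code{"0"}, \code{"1"}, ...), or a single panel containing all gaps.
#' @param cond_A,cond_B,cond_AB condition labels (defaults \code{"+DNAP"},
#'   \code{"+helicase"}, \code{"+both"}).
#' @param z error multiplier for the synergy test.
#' @return List of class \code{"synergy_gap"}: \code{max_gap} (largest
#'   synergistic gap, or \code{"none"} when no gap is synergistic),
#'   \code{per_gap} table, and \code{status} (\code{"ok"} or
#'   \code{"non-monotone"}).
#' @examples
#' panel <- simulate_ap_panel(ap_pattern_synergy(noise = 0), seed = 1)
#' max_synergy_gap(panel)  # max_gap 1
#' @export
max_synergy_gap <- function(panels, cond_A = "+DNAP", cond_B = "+helicase",
                            cond_AB = "+both", z = 2) {
  panel <- if (is.data.frame(panels)) panels
  else do.call(rbind, lapply(panels, as.data.frame))
  gaps <- sort(unique(panel$gap_nt))
  if (!all(0:2 %in% gaps))
    stop("panels for gaps ",
         paste(setdiff(0:2, gaps), collapse = ", "),
         " are required but missing")
  per <- do.call(rbind, lapply(gaps, function(g) {
    sub <- panel[panel$gap_nt == g & panel$context == "junction" &
                   panel$probe_position == g + 1L, ]
    fA <- .panel_folds(sub, cond_A)
    fB <- .panel_folds(sub, cond_B)
    fAB <- .panel_folds(sub, cond_AB)
    s <- detect_synergy(fA$fold, fB$fold, fAB$fold,
                        fA$fold_sd, fB$fold_sd, fAB$fold_sd, z)
    data.frame(gap_nt = g, fold_A = fA$fold, fold_B = fB$fold,
               fold_AB = fAB$fold, synergy = s$synergy,
               margin = s$margin)
  }))
  syn <- per$synergy
  status <- "ok"
  max_gap <- "none"
  if (any(syn)) {
    top <- max(per$gap_nt[syn])
    contiguous <- all(per$synergy[per$gap_nt <= top])
    if (!contiguous) status <- "non-monotone"
    max_gap <- if (contiguous) top else NA_integer_
  }
  structure(list(max_gap = max_gap, per_gap = per, status = status),
            class = "synergy_gap")
}

#' @export
print.synergy_gap <- function(x, ...) {
  print(x$per_gap, row.names = FALSE, digits = 3)
  cat("largest synergistic gap:", format(x$max_gap),
      if (x$status != "ok") paste0("[", x$status, "]") else "", "\n")
  invisible(x)
}
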