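#' Spearman rank correlation
#'
#' Pearson correlation of the rank vectors, with average ranks for ties. A
#' scale-free measure of monotone association: it is invariant under any
#' strictly increasing transform of either input, which makes it the right
#' statistic for relating bond counts to inhibition constants spanning orders
#' of magnitude.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning if either input
#'   is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("at least 3 observations are required")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("constant vector: Spearman correlation is undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Build a variant screen report
#'
#' Aggregates per-variant hydrogen-bond summaries into a ranked table:
#' variants sorted by mean internal bond count (descending, name-order
#' tie-break), percent change of each class mean versus a designated
#' reference variant, joined measured potencies, and the rigidity-potency
#' correlation block (Spearman rho plus Pearson on Ki and on log10 Ki, for
#' internal, intermolecular and total bond counts).
#'
#' @param summaries Either a named list of [summarize_hbonds()] objects
#'   (names = variant labels) or a data frame with columns `variant`,
#'   `internal_mean`, `internal_sem`, `intermolecular_mean`,
#'   `intermolecular_sem`.
#' @param reference Label of the reference variant (must be present).
#' @param potencies Optional data frame `variant`, `ki_nM`, and optionally
#'   `ic50_nM`.
#' @return A tibble of class `screen_report`, sorted, with percent-change and
#'   potency columns; the correlation table is in `attr(, "correlation")` and
#'   via [glance()].
#' @export
build_screen_report <- function(summaries, reference, potencies = NULL) {
  if (is.data.frame(summaries)) {
    tab <- as_tibble(summaries)
    check_cols(tab, c("variant", "internal_mean", "internal_sem",
                      "intermolecular_mean", "intermolecular_sem"))
  } else {
    if (is.null(names(summaries)) || any(names(summaries) == "")) {
      abort("`summaries` list must be named by variant")
    }
    tab <- purrr::imap_dfr(summaries, function(s, nm) {
      cs <- s$class_summary
      pick <- function(cls, col) {
        v <- cs[[col]][cs$bond_class == cls]
        if (length(v) == 0) NA_real_ else v
      }
      tibble(
        variant = nm,
        internal_mean = pick("internal", "mean_count"),
        internal_sem = pick("internal", "sem_count"),
        intermolecular_mean = pick("intermolecular", "mean_count"),
        intermolecular_sem = pick("intermolecular", "sem_count")
      )
    })
  }
  if (anyDuplicated(tab$variant)) abort("duplicate variant names")
  if (!reference %in% tab$variant) {
    abort(paste0("reference variant not found: ", reference))
  }
  ref_row <- tab[tab$variant == reference, ]
  pct_vs_ref <- function(x, ref) {
    if (is.na(ref) || ref <= 0) {
      warn("reference mean is zero or missing; percent change undefined")
      return(rep(NA_real_, length(x)))
    }
    percent_change(x, ref)
  }
  tab <- tab |>
    dplyr::mutate(
      internal_pct_change = pct_vs_ref(.data$internal_mean,
                                       ref_row$internal_mean),
      intermolecular_pct_change = pct_vs_ref(.data$intermolecular_mean,
                                             ref_row$intermolecular_mean)
    ) |>
    dplyr::arrange(dplyr::desc(.data$internal_mean), .data$variant)

  if (!is.null(potencies)) {
    potencies <- as_tibble(potencies)
    check_cols(potencies, c("variant", "ki_nM"))
    if (!"ic50_nM" %in% names(potencies)) potencies$ic50_nM <- NA_real_
    tab <- dplyr::left_join(tab, potencies[c("variant", "ki_nM", "ic50_nM")],
                            by = "variant")
  } else {
    tab$ki_nM <- NA_real_
    tab$ic50_nM <- NA_real_
  }

  with_ki <- dplyr::filter(tab, !is.na(.data$ki_nM))
  correlation <- NULL
  if (nrow(with_ki) >= 3) {
    measures <- list(
      internal = with_ki$internal_mean,
      intermolecular = with_ki$intermolecular_mean,
      total = with_ki$internal_mean + with_ki$intermolecular_mean
    )
    correlation <- purrr::imap_dfr(measures, function(v, nm) {
      tibble(
        measure = nm,
        spearman_rho = spearman_rho(v, with_ki$ki_nM),
        pearson_r_ki = cor(v, with_ki$ki_nM),
        pearson_r_log_ki = cor(v, log10(with_ki$ki_nM)),
        n = nrow(with_ki)
      )
    })
  } else if (!is.null(potencies)) {
    warn("fewer than 3 variants have a Ki; correlation omitted")
  }

  structure(tab, class = c("screen_report", class(tab)),
            reference = reference, correlation = correlation)
}

#' @export
glance.screen_report <- function(x, ...) {
  attr(x, "correlation") %||%
    tibble(measure = character(), spearman_rho = numeric(),
           pearson_r_ki = numeric(), pearson_r_log_ki = numeric(),
           n = integer())
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d variant(s), reference = %s\n",
              nrow(x), attr(x, "reference")))
  NextMethod()
  corr <- attr(x, "correlation")
  if (!is.null(corr)) {
    cat("Rigidity-potency correlation:\n")
    print(corr)
  }
  invisible(x)
}

#' Export a screen report as TSV
#'
#' Columns: `variant`, `internal_mean`, `internal_sem`,
#' `internal_pct_change`, `intermolecular_mean`, `intermolecular_sem`,
#' `intermolecular_pct_change`, `ki_nM`, `ic50_nM`. Means and SEMs are
#' written to 2 decimals, percent changes to 1.
#'
#' @param report A [build_screen_report()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_screen_table <- function(report, path) {
  out <- tibble(
    variant = report$variant,
    internal_mean = sprintf("%.2f", report$internal_mean),
    internal_sem = sprintf("%.2f", report$internal_sem),
    internal_pct_change = sprintf("%.1f", report$internal_pct_change),
    intermolecular_mean = sprintf("%.2f", report$intermolecular_mean),
    intermolecular_sem = sprintf("%.2f", report$intermolecular_sem),
    intermolecular_pct_change = sprintf("%.1f", report$intermolecular_pct_change),
    ki_nM = ifelse(is.na(report$ki_nM), "", format(report$ki_nM)),
    ic50_nM = ifelse(is.na(report$ic50_nM), "", format(report$ic50_nM))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Literature-reported SFTI-FCQR residue-14 screen
#'
#' Reference values from the published screen of SFTI-FCQR (sunflower trypsin
#' inhibitor re-engineered toward KLK4) with every natural amino acid except
#' cysteine substituted at residue 14: replicate-averaged internal and
#' intermolecular hydrogen-bond counts (mean and SEM over three MD replicates)
#' for all nineteen variants, and measured KLK4 potencies (IC50, Morrison Ki,
#' and the competitive-model Ki where determined) for the variants that were
#' synthesised and assayed.
#'
#' @return `sfti_hbond_table()`: a tibble `variant`, `internal_mean`,
#'   `internal_sem`, `intermolecular_mean`, `intermolecular_sem`.
#'   `sfti_potency_table()`: a tibble `variant`, `ic50_nM`, `ki_nM`
#'   (Morrison), `competitive_ki_nM`.
#' @export
sfti_hbond_table <- function() {
  tibble(
    variant = paste0("SFTI-FCQR ", c(
      "Asn14", "Val14", "Tyr14", "Met14", "Lys14", "Phe14", "Ile14", "Asp14",
      "Gly14", "Pro14", "Glu14", "Arg14", "Gln14", "Leu14", "Trp14", "Thr14",
      "Ala14", "Ser14", "His14")),
    internal_mean = c(4.68, 4.26, 4.07, 3.98, 3.91, 3.89, 3.85, 3.70, 3.67,
                      3.66, 3.59, 3.51, 3.36, 3.33, 3.12, 2.93, 2.89, 2.56,
                      2.28),
    internal_sem = c(0.086, 0.14, 0.24, 0.12, 0.47, 0.15, 0.43, 0.11, 0.30,
                     0.43, 0.50, 0.51, 0.25, 0.26, 0.22, 0.093, 0.085, 0.048,
                     0.068),
    intermolecular_mean = c(8.46, 8.17, 8.22, 8.11, 8.11, 7.58, 7.30, 8.28,
                            7.86, 6.49, 7.83, 7.65, 7.52, 8.11, 7.92, 7.34,
                            7.25, 7.52, 8.07),
    intermolecular_sem = c(0.10, 0.18, 0.30, 0.20, 0.17, 0.08, 0.35, 0.19,
                           0.17, 0.23, 0.36, 0.04, 0.14, 0.17, 0.36, 0.06,
                           0.16, 0.10, 0.11)
  )
}

#' @rdname sfti_hbond_table
#' @export
sfti_potency_table <- function() {
  tibble(
    variant = paste0("SFTI-FCQR ", c("Asn14", "Tyr14", "Lys14", "Asp14",
                                     "Gly14", "Ala14", "Ser14")),
    ic50_nM = c(0.0635, 3.47, 6.07, 7.97, 14.74, 26.23, 29.23),
    ki_nM = c(0.0386, 2.55, 3.56, 3.89, 10.39, 18.31, 21.24),
    competitive_ki_nM = c(NA, NA, NA, 3.62, NA, NA, NA)
  )
}
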