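#' RFLP assay registry
#'
#' The three restriction-digest assays used to genotype the cohort. Each
#' amplicon is digested by an enzyme that cuts exactly one allele:
#'
#' * `CYP2C9_star2_AvaII` — 454 bp exon-3 amplicon; AvaII cuts the wild-type
#'   allele into 397 + 57 bp, so an uncut 454 bp band marks the *2 allele.
#' * `CYP2C9_star3_KpnI` — 105 bp exon-7 amplicon; KpnI cuts the *3 (variant)
#'   allele into 85 + 20 bp.
#' * `VKORC1_1639_MspI` — 290 bp promoter amplicon; MspI cuts the wild-type G
#'   allele into 167 + 123 bp, the -1639A allele stays uncut.
#'
#' @return A tibble with columns `name`, `amplicon_bp`, `cut_fragments_bp`
#'   (list of integer vectors), `cut_allele` (`"wild_type"` or `"variant"`)
#'   and `locus`.
#' @export
rflp_assays <- function() {
  tibble::tibble(
    name = c("CYP2C9_star2_AvaII", "CYP2C9_star3_KpnI", "VKORC1_1639_MspI"),
    locus = c("cyp2c9_star2", "cyp2c9_star3", "vkorc1"),
    amplicon_bp = c(454L, 105L, 290L),
    cut_fragments_bp = list(c(397L, 57L), c(85L, 20L), c(167L, 123L)),
    cut_allele = c("wild_type", "variant", "wild_type")
  )
}

rflp_assay <- function(name) {
  assays <- rflp_assays()
  i <- match(name, assays$name)
  if (is.na(i)) {
    abort(sprintf("unknown RFLP assay '%s'", name), class = "warfpgx_schema_error")
  }
  assays[i, ]
}

# Genotype labels indexed by variant-allele copy number (1 + copies).
rflp_labels <- list(
  cyp2c9_star2 = c("*1/*1", "*1/*2", "*2/*2"),
  cyp2c9_star3 = c("*1/*1", "*1/*3", "*3/*3"),
  vkorc1 = c("GG", "GA", "AA")
)

no_call <- function(diagnostic) {
  structure(NA_character_, diagnostic = diagnostic)
}

#' Call a genotype from an observed restriction-fragment pattern
#'
#' Interprets a set of band sizes from one digest lane. A cut-only pattern is
#' homozygous for the allele the enzyme cuts, an uncut-only pattern is
#' homozygous for the other allele, and the combined pattern is heterozygous;
#' `cut_allele` of the assay orients the call to reference/variant. Fragments
#' shorter than `min_resolved_bp` routinely run off the agarose gels used for
#' these digests, so a pattern missing only sub-resolution bands still calls
#' when unambiguous.
#'
#' @param assay Assay name (see [rflp_assays()]) or a one-row assay tibble.
#' @param observed_fragments_bp Integer vector of observed band sizes.
#' @param min_resolved_bp Bands below this size (default 60 bp) are optional.
#' @return The genotype label (e.g. `"*1/*2"`, `"GA"`), or `NA` with a
#'   `diagnostic` attribute when the pattern cannot be interpreted.
#' @export
#' @examples
#' call_rflp_genotype("CYP2C9_star2_AvaII", c(397, 57)) # "*1/*1"
#' call_rflp_genotype("VKORC1_1639_MspI", c(290, 167, 123)) # "GA"
call_rflp_genotype <- function(assay, observed_fragments_bp,
                               min_resolved_bp = 60) {
  if (is.character(assay)) assay <- rflp_assay(assay)
  frags <- unique(as.integer(observed_fragments_bp))
  frags <- frags[!is.na(frags)]
  cut_frags <- assay$cut_fragments_bp[[1]]
  if (length(frags) == 0) {
    return(no_call("empty fragment set"))
  }
  unknown <- setdiff(frags, c(assay$amplicon_bp, cut_frags))
  if (length(unknown) > 0) {
    return(no_call(sprintf(
      "unrecognized fragment length(s) for %s: %s",
      assay$name, paste(unknown, collapse = ", ")
    )))
  }
  uncut <- assay$amplicon_bp %in% frags
  cut_seen <- intersect(frags, cut_frags)
  cut <- length(cut_seen) > 0
  if (cut) {
    required <- cut_frags[cut_frags >= min_resolved_bp]
    if (!all(required %in% frags)) {
      return(no_call(sprintf(
        "incomplete digest pattern for %s: missing %s bp",
        assay$name, paste(setdiff(required, frags), collapse = ", ")
      )))
    }
  }
  cut_copies <- if (cut && uncut) 1L else if (cut) 2L else 0L
  variant_copies <- if (assay$cut_allele == "variant") cut_copies else 2L - cut_copies
  rflp_labels[[assay$locus]][variant_copies + 1L]
}

#' Combine the two CYP2C9 assay calls into a diplotype
#'
#' The AvaII assay types the *2 site and the KpnI assay the *3 site; together
#' they determine the six-class IWPC diplotype. An `NA` from either assay
#' propagates to an `"unknown"` diplotype; more than two variant copies in
#' total is biologically impossible and raises a record-level error.
#'
#' @param star2 Call from the AvaII assay (`"*1/*1"`, `"*1/*2"`, `"*2/*2"` or `NA`).
#' @param star3 Call from the KpnI assay (`"*1/*1"`, `"*1/*3"`, `"*3/*3"` or `NA`).
#' @return A diplotype from the CYP2C9 vocabulary.
#' @export
combine_cyp2c9 <- function(star2, star3) {
  if (is.na(star2) || is.na(star3)) {
    return("unknown")
  }
  c2 <- match(star2, rflp_labels$cyp2c9_star2) - 1L
  c3 <- match(star3, rflp_labels$cyp2c9_star3) - 1L
  if (is.na(c2) || is.na(c3)) {
    abort("invalid single-site CYP2C9 call", class = "warfpgx_record_error")
  }
  if (c2 + c3 > 2L) {
    abort("inconsistent CYP2C9 assay calls: more than two variant alleles",
      class = "warfpgx_record_error"
    )
  }
  key <- paste(c2, c3)
  switch(key,
    "0 0" = "*1/*1", "1 0" = "*1/*2", "0 1" = "*1/*3",
    "2 0" = "*2/*2", "1 1" = "*2/*3", "0 2" = "*3/*3"
  )
}

#' Call per-patient genotypes from a fragment-observation table
#'
#' @param fragments A tibble/data frame with columns `id`, `assay` and
#'   `fragments_bp` (comma-joined band sizes, e.g. `"454,397,57"`), typically
#'   read from the fragments CSV written by [generate_fixture_files()].
#' @return A tibble with one row per patient: `id`, `cyp2c9`, `vkorc1`.
#' @export
call_genotypes_from_fragments <- function(fragments) {
  needed <- c("id", "assay", "fragments_bp")
  missing_cols <- setdiff(needed, names(fragments))
  if (length(missing_cols) > 0) {
    abort(
      paste0("fragments table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "warfpgx_schema_error"
    )
  }
  fragments$call <- purrr::map2_chr(
    fragments$assay, fragments$fragments_bp,
    function(a, f) {
      sizes <- as.integer(strsplit(f, ",", fixed = TRUE)[[1]])
      as.character(call_rflp_genotype(a, sizes))
    }
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(fragments, "id", "assay", "call"),
    names_from = "assay", values_from = "call"
  )
  star2 <- wide[["CYP2C9_star2_AvaII"]] %||% rep(NA_character_, nrow(wide))
  star3 <- wide[["CYP2C9_star3_KpnI"]] %||% rep(NA_character_, nrow(wide))
  tibble::tibble(
    id = wide$id,
    cyp2c9 = purrr::map2_chr(star2, star3, combine_cyp2c9),
    vkorc1 = dplyr::coalesce(wide[["VKORC1_1639_MspI"]], "unknown")
  )
}

#' Genotype counts at one biallelic locus
#'
#' @param hom_ref,het,hom_var Non-negative genotype counts (homozygous
#'   reference, heterozygous, homozygous variant).
#' @param locus Optional locus label.
#' @return A `warf_genotype_counts` object.
#' @export
genotype_counts <- function(hom_ref, het, hom_var, locus = "") {
  counts <- c(hom_ref = hom_ref, het = het, hom_var = hom_var)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers",
      class = "warfpgx_schema_error"
    )
  }
  structure(
    list(locus = locus, counts = counts, total = sum(counts)),
    class = "warf_genotype_counts"
  )
}

#' Tally genotype counts for a cohort at one locus
#'
#' Counts copies of one variant allele. For CYP2C9 the diplotype is reduced to
#' the copy number of the requested allele (`"*2"` or `"*3"`); e.g. `"*2/*3"`
#' counts as heterozygous for either. Patients with `"unknown"` genotype are
#' excluded from the tally.
#'
#' @param cohort A `warf_cohort`.
#' @param locus `"cyp2c9"` or `"vkorc1"`.
#' @param variant Variant allele counted for CYP2C9 (default `"*2"`).
#' @return A `warf_genotype_counts` object.
#' @export
genotype_counts_from_cohort <- function(cohort, locus = c("cyp2c9", "vkorc1"),
                                        variant = "*2") {
  locus <- match.arg(locus)
  g <- cohort[[locus]]
  g <- g[!is.na(g) & g != "unknown"]
  copies <- if (locus == "vkorc1") {
    c(GG = 0L, GA = 1L, AA = 2L)[g]
  } else {
    alleles <- strsplit(sub("^\\*", "", gsub("/\\*", "/", g)), "/", fixed = TRUE)
    vapply(alleles, function(a) sum(paste0("*", a) == variant), integer(1))
  }
  tab <- tabulate(copies + 1L, nbins = 3L)
  genotype_counts(tab[1], tab[2], tab[3],
    locus = if (locus == "vkorc1") "VKORC1" else paste0("CYP2C9", variant)
  )
}

#' Genotype relative frequencies
#'
#' @param counts A `warf_genotype_counts` object (or numeric length-3 vector).
#' @return Named proportions summing to 1.
#' @export
genotype_frequencies <- function(counts) {
  counts <- as_genotype_counts(counts)
  if (counts$total == 0) {
    abort("no genotyped individuals", class = "warfpgx_degenerate")
  }
  counts$counts / counts$total
}

#' Allele frequencies by direct gene counting
#'
#' Variant frequency is `(het + 2 * hom_var) / (2 * total)`.
#'
#' @inheritParams genotype_frequencies
#' @return Named vector `c(reference = ..., variant = ...)`, summing to 1.
#' @export
allele_frequencies <- function(counts) {
  counts <- as_genotype_counts(counts)
  if (counts$total == 0) {
    abort("no genotyped individuals", class = "warfpgx_degenerate")
  }
  q <- (counts$counts[["het"]] + 2 * counts$counts[["hom_var"]]) / (2 * counts$total)
  c(reference = 1 - q, variant = q)
}

as_genotype_counts <- function(x) {
  if (inherits(x, "warf_genotype_counts")) {
    return(x)
  }
  if (is.numeric(x) && length(x) == 3) {
    return(genotype_counts(x[1], x[2], x[3]))
  }
  abort("expected a warf_genotype_counts or a length-3 count vector",
    class = "warfpgx_schema_error"
  )
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit of the observed genotype counts against the
#' p^2 / 2pq / q^2 expectation computed from the gene-counting allele
#' frequencies; 1 degree of freedom (three classes, one estimated allele
#' frequency), no continuity correction. A monomorphic locus has nothing to
#' test: the result is flagged and reported as chi-square 0, p 1.
#'
#' @inheritParams genotype_frequencies
#' @return A `warf_hwe` list: `chi_square`, `df`, `p_value`,
#'   `expected_counts`, `monomorphic`.
#' @export
#' @examples
#' hwe_chi_square(genotype_counts(75, 25, 1))
hwe_chi_square <- function(counts) {
  counts <- as_genotype_counts(counts)
  if (counts$total == 0) {
    abort("no genotyped individuals", class = "warfpgx_degenerate")
  }
  q <- allele_frequencies(counts)[["variant"]]
  p <- 1 - q
  expected <- counts$total * c(hom_ref = p^2, het = 2 * p * q, hom_var = q^2)
  if (q == 0 || q == 1) {
    res <- list(
      chi_square = 0, df = 1L, p_value = 1,
      expected_counts = expected, monomorphic = TRUE
    )
    return(structure(res, class = "warf_hwe"))
  }
  stat <- sum((counts$counts - expected)^2 / expected)
  structure(
    list(
      chi_square = stat, df = 1L,
      p_value = pchisq(stat, df = 1, lower.tail = FALSE),
      expected_counts = expected, monomorphic = FALSE
    ),
    class = "warf_hwe"
  )
}

#' @export
print.warf_hwe <- function(x, ...) {
  cat(sprintf(
    "Hardy-Weinberg chi-square = %.3f (df = %d), p = %.3f%s\n",
    x$chi_square, x$df, x$p_value,
    if (x$monomorphic) " [monomorphic locus]" else ""
  ))
  invisible(x)
}
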