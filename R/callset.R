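#' Multi-sample callset container
#'
#' A `callset` bundles one decomposed variant site per row with the
#' per-sample genotype matrix of a targeted-panel cohort. Genotypes are
#' stored as alternate-allele dosages (`0`, `1`, `2`, `NA` = missing)
#' together with the call ploidy (2 for diploid calls, 1 for hemizygous
#' calls) and per-genotype quality (GQ). Each variant carries two filter
#' statuses, one per reference build, read from a sidecar table; a site is
#' only trusted downstream when both builds agree it passed
#' (see [apply_consensus_filter()]).
#'
#' @param variants data.frame with columns `key`, `chrom`, `pos`, `ref`,
#'   `alt`, `filter_build_a`, `filter_build_b`
#' @param dosage integer matrix (sites x samples) of alt-allele dosages
#' @param gq integer matrix (sites x samples) of genotype qualities
#' @param ploidy integer matrix (sites x samples), 1 or 2
#' @param samples character vector of sample ids (column order)
#' @return an object of class `callset`
#' @export
new_callset <- function(variants, dosage, gq, ploidy, samples) {
  req <- c("key", "chrom", "pos", "ref", "alt", "filter_build_a", "filter_build_b")
  stopifnot(
    is.data.frame(variants), all(req %in% names(variants)),
    is.matrix(dosage), is.matrix(gq), is.matrix(ploidy),
    nrow(dosage) == nrow(variants), ncol(dosage) == length(samples),
    all(dim(gq) == dim(dosage)), all(dim(ploidy) == dim(dosage)),
    !anyDuplicated(samples)
  )
  if (any(!nzchar(variants$filter_build_a)) || any(!nzchar(variants$filter_build_b))) {
    stop("filter statuses must be non-empty strings")
  }
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  rownames(dosage) <- rownames(gq) <- rownames(ploidy) <- variants$key
  colnames(dosage) <- colnames(gq) <- colnames(ploidy) <- samples
  structure(
    list(variants = variants, dosage = dosage, gq = gq, ploidy = ploidy,
         samples = samples),
    class = "callset"
  )
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}

#' Number of variants in a callset
#' @param cs a [new_callset()] object
#' @export
n_variants <- function(cs) nrow(cs$variants)

#' Subset a callset by variant index
#' @param cs a callset
#' @param i logical or integer index over variants
#' @export
subset_callset <- function(cs, i) {
  new_callset(cs$variants[i, , drop = FALSE],
              cs$dosage[i, , drop = FALSE],
              cs$gq[i, , drop = FALSE],
              cs$ploidy[i, , drop = FALSE],
              cs$samples)
}

#' Subset a callset by sample ids
#' @param cs a callset
#' @param keep character vector of sample ids to retain
#' @export
subset_samples <- function(cs, keep) {
  j <- match(keep, cs$samples)
  if (anyNA(j)) stop("unknown sample ids: ", paste(keep[is.na(j)], collapse = ", "))
  new_callset(cs$variants,
              cs$dosage[, j, drop = FALSE],
              cs$gq[, j, drop = FALSE],
              cs$ploidy[, j, drop = FALSE],
              cs$samples[j])
}

#' Is a chromosome label the X chromosome?
#' @param chrom character vector of chromosome labels
#' @return logical vector (`"X"`, `"chrX"` and `"23"` count as X)
#' @export
is_chrx <- function(chrom) chrom %in% c("X", "chrX", "23")

# Parse a GT character matrix (VCF conventions) into dosage/ploidy for one
# alternate allele index. Unphased and phased separators both accepted.
parse_gt_matrix <- function(gt, alt_index) {
  flat <- as.vector(gt)
  toks <- strsplit(flat, "[/|]", fixed = FALSE)
  dos <- vapply(toks, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
    sum(a == as.character(alt_index))
  }, integer(1))
  pld <- vapply(toks, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
    length(a)
  }, integer(1))
  list(dosage = matrix(dos, nrow(gt), ncol(gt)),
       ploidy = matrix(pld, nrow(gt), ncol(gt)))
}

#' Read a multi-sample VCF and its dual-build filter sidecar
#'
#' Reads a VCF 4.2 file (gzip accepted) with `GT` and `GQ` FORMAT fields
#' and a tab-separated sidecar table carrying the per-variant filter
#' status under each of the two reference builds. Multi-allelic rows are
#' decomposed into one record per alternate allele; other alternate
#' alleles count as reference in the decomposed record, so total
#' alternate dosage per sample per site is preserved across the
#' decomposition.
#'
#' @param vcf_path path to the VCF
#' @param filter_table_path path to a TSV with columns `variant_key`,
#'   `filter_build_a`, `filter_build_b`; every decomposed VCF record must
#'   have a matching key
#' @return a [new_callset()] object, sample order as in the VCF header
#' @export
read_callset <- function(vcf_path, filter_table_path) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  # index the fixed-field matrix directly: getFIX() drops to a vector
  # when the VCF holds a single record
  fix <- as.data.frame(vcf@fix[, 1:7, drop = FALSE], stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq_raw <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  rows <- list(); dos <- list(); pld <- list(); gqs <- list()
  for (i in seq_len(nrow(fix))) {
    for (k in seq_along(alts[[i]])) {
      g <- parse_gt_matrix(gt[i, , drop = FALSE], k)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[[i]][k], stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- g$dosage
      pld[[length(pld) + 1L]] <- g$ploidy
      gqs[[length(gqs) + 1L]] <- gq_raw[i, , drop = FALSE]
    }
  }
  variants <- do.call(rbind, rows)
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)

  ft <- read.delim(filter_table_path, stringsAsFactors = FALSE)
  req <- c("variant_key", "filter_build_a", "filter_build_b")
  if (!all(req %in% names(ft))) {
    stop("filter table must have columns: ", paste(req, collapse = ", "))
  }
  m <- match(variants$key, ft$variant_key)
  if (anyNA(m)) {
    stop("filter table has no entry for VCF record(s): ",
         paste(variants$key[is.na(m)], collapse = ", "))
  }
  variants$filter_build_a <- ft$filter_build_a[m]
  variants$filter_build_b <- ft$filter_build_b[m]
  dosage <- do.call(rbind, dos)
  gq <- do.call(rbind, gqs)
  gq[is.na(dosage)] <- NA_integer_
  new_callset(variants[, c("key", "chrom", "pos", "ref", "alt",
                           "filter_build_a", "filter_build_b")],
              dosage, matrix(as.integer(gq), nrow(dosage)),
              do.call(rbind, pld), samples)
}

gt_string <- function(dosage, ploidy) {
  out <- character(length(dosage))
  out[is.na(dosage)] <- "./."
  d2 <- !is.na(dosage) & ploidy == 2L
  out[d2] <- c("0/0", "0/1", "1/1")[dosage[d2] + 1L]
  d1 <- !is.na(dosage) & ploidy == 1L
  out[d1] <- as.character(dosage[d1])
  out
}

#' Write a callset as VCF plus filter sidecar
#'
#' Emits a minimal VCF 4.2 (FORMAT `GT:GQ`, FILTER column `.`) and the
#' dual-build filter sidecar consumed by [read_callset()].
#'
#' @param cs a callset
#' @param vcf_path,filter_table_path output paths
#' @return invisibly, the two paths
#' @export
write_callset <- function(cs, vcf_path, filter_table_path) {
  v <- cs$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cs$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    gts <- gt_string(cs$dosage[i, ], cs$ploidy[i, ])
    gq <- ifelse(is.na(cs$gq[i, ]), ".", as.character(cs$gq[i, ]))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", ".", ".",
            "GT:GQ",
            paste(gts, gq, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf_path)
  write.table(
    data.frame(variant_key = v$key, filter_build_a = v$filter_build_a,
               filter_build_b = v$filter_build_b),
    filter_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf_path, filter_table_path))
}

#' Consensus quality filter across two reference builds
#'
#' A variant is retained only when its filter status is `PASS` under both
#' reference builds and every genotype carrying an alternate allele has
#' genotype quality at least `gq_required`. With the default
#' `gq_required = 99` (the GQ ceiling), this demands maximal quality for
#' all non-reference genotypes — a conservative rule aimed at minimizing
#' false positive calls in catalog studies.
#'
#' @param cs a callset
#' @param gq_required minimum GQ demanded of non-reference genotypes
#' @return a list with elements `callset` (retained records) and
#'   `rejections` (data.frame `key`, `reason` in
#'   `"build_a"`/`"build_b"`/`"GQ"`; the first failed criterion is logged)
#' @export
apply_consensus_filter <- function(cs, gq_required = 99) {
  v <- cs$variants
  ok_a <- v$filter_build_a == "PASS"
  ok_b <- v$filter_build_b == "PASS"
  nonref <- !is.na(cs$dosage) & cs$dosage >= 1L
  gq_bad <- !is.na(cs$dosage) & nonref & (is.na(cs$gq) | cs$gq < gq_required)
  ok_gq <- rowSums(gq_bad) == 0L
  keep <- ok_a & ok_b & ok_gq
  reason <- ifelse(!ok_a, "build_a", ifelse(!ok_b, "build_b", "GQ"))
  rejections <- data.frame(key = v$key[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
  list(callset = subset_callset(cs, keep), rejections = rejections)
}

#' Per-site allele counts and frequencies
#'
#' Computes alternate allele count (AC), total called alleles (AN) and
#' allele frequency (AF = AC/AN) per decomposed site. Autosomal samples
#' contribute two alleles when called; missing genotypes reduce AN. On
#' chromosome X the default sex-aware policy makes male samples
#' contribute one allele (hemizygous; a diploid-coded male alt genotype
#' counts one alt copy); samples of unknown sex are treated as diploid
#' with a warning. `chrx_policy = "diploid"` disables the sex adjustment.
#'
#' @param cs a callset
#' @param sample_info optional data.frame with `sample_id`, `sex`
#'   (required for the sex-aware X policy)
#' @param chrx_policy `"sex_aware"` (default) or `"diploid"`
#' @return data.frame `key`, `ac`, `an`, `af`
#' @export
compute_site_counts <- function(cs, sample_info = NULL,
                                chrx_policy = c("sex_aware", "diploid")) {
  chrx_policy <- match.arg(chrx_policy)
  dosage <- cs$dosage
  ploidy <- cs$ploidy
  x_rows <- is_chrx(cs$variants$chrom)
  if (chrx_policy == "sex_aware" && any(x_rows)) {
    if (is.null(sample_info)) {
      warning("sex-aware chrX policy without sample_info; treating all as diploid")
    } else {
      sex <- sample_info$sex[match(cs$samples, sample_info$sample_id)]
      if (any(is.na(sex) | sex == "unknown")) {
        warning("samples with unknown sex treated as diploid on chrX")
      }
      male <- !is.na(sex) & sex == "male"
      if (any(male)) {
        ploidy[x_rows, male] <- 1L
        dosage[x_rows, male] <- pmin(dosage[x_rows, male], 1L)
      }
    }
  }
  called <- !is.na(dosage)
  an <- as.integer(rowSums(ploidy * called, na.rm = TRUE))
  ac <- as.integer(rowSums(dosage, na.rm = TRUE))
  data.frame(key = cs$variants$key, ac = ac, an = an,
             af = ifelse(an > 0, ac / an, NA_real_),
             stringsAsFactors = FALSE)
}
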