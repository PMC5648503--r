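# Feature annotation tables are plain data.frames with columns
# feature_id, chrom, pos (1-based). Expression/methylation stores are named
# lists of subjects x tissues matrices keyed by feature id; genotype stores
# are SNP x subject matrices of 0/1/2 dosages.

.check_annot <- function(x, what) {
  need <- c("feature_id", "chrom", "pos")
  if (!all(need %in% names(x)))
    stop(what, " annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$feature_id))
    stop("duplicate feature ids in ", what, " annotation")
  if (any(x$pos < 1)) stop(what, " positions must be 1-based (>= 1)")
  x
}

#' Enumerate cis (transcript, CpG, SNP) candidate triplets
#'
#' A CpG is paired with a transcript when it lies strictly within
#' `cpg_window_bp` of the transcription start site (|cpg - tss| <
#' `cpg_window_bp`); a SNP is cis to the transcript when its distance to the
#' TSS does not exceed `snp_window_bp` (|snp - tss| <= `snp_window_bp`).
#' Matching is within-chromosome only. Every (transcript, CpG) pair combines
#' with each of the transcript's cis-SNPs, so a transcript with 2 promoter
#' CpGs and 2 cis-SNPs yields 4 triplets.
#'
#' @param transcripts,cpgs,snps data.frames with columns `feature_id`,
#'   `chrom`, `pos` (transcript `pos` is its TSS).
#' @param snp_window_bp cis window around the TSS for SNPs (inclusive
#'   boundary); default 100 kb.
#' @param cpg_window_bp promoter window for CpGs (exclusive boundary);
#'   default 1.5 kb.
#' @return data.frame with columns `transcript_id`, `cpg_id`, `snp_id`.
#' @export
pair_cis <- function(transcripts, cpgs, snps,
                     snp_window_bp = 100000, cpg_window_bp = 1500) {
  transcripts <- .check_annot(as.data.frame(transcripts), "transcript")
  cpgs <- .check_annot(as.data.frame(cpgs), "cpg")
  snps <- .check_annot(as.data.frame(snps), "snp")
  out <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    tss <- transcripts$pos[i]
    chrom <- transcripts$chrom[i]
    cc <- cpgs$feature_id[cpgs$chrom == chrom &
                          abs(cpgs$pos - tss) < cpg_window_bp]
    ss <- snps$feature_id[snps$chrom == chrom &
                          abs(snps$pos - tss) <= snp_window_bp]
    if (length(cc) && length(ss)) {
      grid <- expand.grid(cpg_id = cc, snp_id = ss,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      out[[i]] <- data.frame(transcript_id = transcripts$feature_id[i],
                             grid, stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(transcript_id = character(), cpg_id = character(),
                      snp_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Scan cis triplets with a multi-tissue or tissue-by-tissue test
#'
#' Runs the chosen test over every (transcript, CpG, SNP) triplet. For the
#' joint score test the null model is fitted once per (transcript, CpG)
#' pair and reused across that pair's cis-SNPs; for the methylation-free
#' joint test, once per transcript. p-values are pooled over the whole scan
#' and converted to q-values with [qvalues()]; a triplet is significant at
#' `q <= fdr`. Tissue-by-tissue modes instead compute per-tissue q-values
#' over the scan, take the minimum q across tissues, and declare
#' significance at `q <= fdr / t`.
#'
#' For joint-test scans, each significant triplet carries driver flags
#' indicating which score components (additive, G-by-M, G-by-T,
#' G-by-M-by-T) are marginally significant at 0.05.
#'
#' @param expr named list of n x t expression matrices, keyed by transcript.
#' @param meth named list of n x t methylation matrices, keyed by CpG.
#' @param geno SNP x subject matrix of 0/1/2 dosages with SNP row names.
#' @param triplets data.frame from [pair_cis()].
#' @param method one of `"joint"`, `"jaguar"`, `"tbt"`, `"tbtm"`.
#' @param fdr false discovery rate for the significance call.
#' @return data.frame with one row per tested triplet: `p_value`,
#'   `q_value`, `significant`, and (joint method) component p-values and
#'   driver flags.
#' @export
scan_triplets <- function(expr, meth, geno, triplets,
                          method = c("joint", "jaguar", "tbt", "tbtm"),
                          fdr = 0.05) {
  method <- match.arg(method)
  triplets <- as.data.frame(triplets)
  if (!nrow(triplets))
    return(data.frame(transcript_id = character(), cpg_id = character(),
                      snp_id = character(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  keep <- triplets$transcript_id %in% names(expr) &
    triplets$cpg_id %in% names(meth) &
    triplets$snp_id %in% rownames(geno)
  if (any(!keep)) {
    warning(sum(!keep), " triplet(s) skipped: features missing from stores")
    triplets <- triplets[keep, , drop = FALSE]
  }
  if (!nrow(triplets))
    return(data.frame(transcript_id = character(), cpg_id = character(),
                      snp_id = character(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  # stable processing order regardless of input row order
  ord <- order(triplets$transcript_id, triplets$cpg_id, triplets$snp_id)
  triplets <- triplets[ord, , drop = FALSE]
  rownames(triplets) <- NULL
  n_trip <- nrow(triplets)

  if (method %in% c("joint", "jaguar")) {
    pair_key <- if (method == "joint")
      paste(triplets$transcript_id, triplets$cpg_id, sep = "\r")
    else triplets$transcript_id
    res <- data.frame(triplets, p_value = NA_real_,
                      p_additive = NA_real_, p_gxm = NA_real_,
                      p_gxt = NA_real_, p_gxmxt = NA_real_)
    for (key in unique(pair_key)) {
      rows <- which(pair_key == key)
      tr <- triplets$transcript_id[rows[1]]
      y <- expr[[tr]]
      fit <- if (method == "joint")
        fit_null(y, meth[[triplets$cpg_id[rows[1]]]])
      else fit_null(y, m = NULL)
      for (r in rows) {
        g <- as.numeric(geno[triplets$snp_id[r], ])
        tst <- combine_and_test(fit, efficient_scores(fit, g))
        res$p_value[r] <- tst$p_value
        cp <- tst$component_p
        res$p_additive[r] <- cp["beta"]
        res$p_gxt[r] <- cp["gamma"]
        if (method == "joint") {
          res$p_gxm[r] <- cp["phi"]
          res$p_gxmxt[r] <- cp["delta"]
        }
      }
    }
    res$q_value <- qvalues(res$p_value)
    res$significant <- res$q_value <= fdr
    res$driver_additive <- res$significant & res$p_additive < 0.05
    res$driver_gxt <- res$significant & res$p_gxt < 0.05
    if (method == "joint") {
      res$driver_gxm <- res$significant & res$p_gxm < 0.05
      res$driver_gxmxt <- res$significant & res$p_gxmxt < 0.05
    }
    return(res)
  }

  # tissue-by-tissue modes: per-tissue p, per-tissue q over the scan,
  # min q across tissues, significance at fdr / t
  t_n <- ncol(expr[[triplets$transcript_id[1]]])
  pmat <- matrix(NA_real_, n_trip, t_n)
  for (r in seq_len(n_trip)) {
    y <- expr[[triplets$transcript_id[r]]]
    g <- as.numeric(geno[triplets$snp_id[r], ])
    tb <- if (method == "tbt") tbt_eqtl(y, g)
          else tbtm_eqtl(y, g, meth[[triplets$cpg_id[r]]])
    pmat[r, ] <- tb$per_tissue_p
  }
  qmat <- apply(pmat, 2, qvalues)
  min_q <- apply(qmat, 1, min)
  data.frame(triplets,
             p_value = apply(pmat, 1, min),
             q_value = min_q,
             significant = min_q <= fdr / t_n)
}

# --- plain-text stores ------------------------------------------------------

#' Read or write a feature-by-tissue matrix store
#'
#' The TSV layout has one row per feature x tissue: columns `feature_id`,
#' `tissue`, then one column per sample. `read_matrix_store()` returns a
#' named list of subjects x tissues matrices (samples in file column order,
#' tissues in first-appearance order).
#'
#' @param path TSV file path.
#' @return named list of numeric matrices.
#' @export
read_matrix_store <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "tissue") %in% names(tab)))
    stop("store must have feature_id and tissue columns")
  samples <- setdiff(names(tab), c("feature_id", "tissue"))
  out <- lapply(split(tab, tab$feature_id), function(d) {
    m <- t(as.matrix(d[, samples, drop = FALSE]))
    colnames(m) <- d$tissue
    rownames(m) <- samples
    m
  })
  out
}

#' @rdname read_matrix_store
#' @param store named list of subjects x tissues matrices.
#' @export
write_matrix_store <- function(store, path) {
  rows <- lapply(names(store), function(id) {
    m <- store[[id]]
    tiss <- colnames(m)
    if (is.null(tiss)) tiss <- paste0("tissue", seq_len(ncol(m)))
    d <- data.frame(feature_id = id, tissue = tiss, t(m), check.names = FALSE)
    d
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a genotype dosage store
#'
#' TSV with one row per SNP: `feature_id` column then one 0/1/2 dosage
#' column per sample.
#'
#' @param path TSV file path.
#' @return integer matrix, SNPs x subjects, with SNP row names.
#' @export
read_genotype_store <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(tab)) stop("genotype store needs feature_id column")
  m <- as.matrix(tab[, setdiff(names(tab), "feature_id"), drop = FALSE])
  rownames(m) <- tab$feature_id
  if (!all(m %in% 0:2)) stop("genotype dosages must be 0, 1 or 2")
  m
}

#' @rdname read_genotype_store
#' @param geno SNP x subject dosage matrix with row names.
#' @export
write_genotype_store <- function(geno, path) {
  d <- data.frame(feature_id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' TSV with columns `feature_id`, `chrom`, `pos` and optionally `kind`
#' (transcript / cpg / snp).
#'
#' @param path TSV file path.
#' @param kind optional filter on the `kind` column.
#' @return data.frame.
#' @export
read_annotations <- function(path, kind = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(kind)) {
    if (!"kind" %in% names(tab)) stop("annotation file has no kind column")
    tab <- tab[tab$kind == kind, , drop = FALSE]
  }
  .check_annot(tab, if (is.null(kind)) "feature" else kind)
}
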