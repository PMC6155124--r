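#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_i is the minimum over j with p_(j) >= p_(i) of
#' n * p_(j) / j, capped at 1, returned in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (no missing values).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0) || any(pvalues > 1)) {
    stop("bh_fdr: all p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Merged differential statistic
#'
#' Combines effect size and significance into one signed ordinal value:
#' `D = log2fc * (-log10(max(qvalue, q_floor)))`. The statistic carries the
#' sign of the fold-change and grows with both |log2fc| and significance.
#' `q_floor` keeps D finite when an upstream tool reports q = 0.
#'
#' @param log2fc numeric log2 fold-change(s).
#' @param qvalue FDR-adjusted p-value(s) in `[0, 1]`.
#' @param q_floor smallest q used in the logarithm (default 1e-300).
#' @param log_base base of the significance logarithm (default 10). The
#'   statistic is used ordinally, so the base rescales without reordering.
#' @return numeric vector of merged statistics.
#' @export
merged_statistic <- function(log2fc, qvalue, q_floor = 1e-300, log_base = 10) {
  if (anyNA(qvalue) || any(qvalue < 0) || any(qvalue > 1)) {
    stop("merged_statistic: qvalue must be in [0, 1]")
  }
  if (q_floor <= 0 && any(qvalue == 0)) {
    stop("merged_statistic: q = 0 with q_floor = 0 gives an infinite statistic")
  }
  log2fc * (-log(pmax(qvalue, q_floor), base = log_base))
}

#' Build a differential table with q-values and merged statistic
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param log2fc,pvalue per-gene effect and raw p-value.
#' @param qvalue optional pre-computed FDR column; if `NULL`, computed with
#'   [bh_fdr()].
#' @param q_floor,log_base passed to [merged_statistic()].
#' @return data.frame with columns gene_id, log2fc, pvalue, qvalue, D.
#' @export
differential_table <- function(gene_id, log2fc, pvalue, qvalue = NULL,
                               q_floor = 1e-300, log_base = 10) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids")
  if (is.null(qvalue)) qvalue <- bh_fdr(pvalue)
  data.frame(gene_id = as.character(gene_id), log2fc = log2fc,
             pvalue = pvalue, qvalue = qvalue,
             D = merged_statistic(log2fc, qvalue, q_floor, log_base),
             stringsAsFactors = FALSE)
}

#' Read a differential-expression table (TSV/CSV with header)
#'
#' Expects columns `gene_id`, `log2fc`, `pvalue` and optionally `qvalue`
#' (either edgeR's FDR or cuffdiff's q may populate it); missing q-values are
#' filled with [bh_fdr()] and the merged statistic D is appended.
#'
#' @param path file path; comma- or tab-delimited, with header.
#' @param q_floor,log_base passed to [merged_statistic()].
#' @return data.frame as from [differential_table()].
#' @export
read_differential <- function(path, q_floor = 1e-300, log_base = 10) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(df))) {
    stop("differential table must have columns: ", paste(need, collapse = ", "))
  }
  differential_table(df$gene_id, df$log2fc, df$pvalue,
                     qvalue = if ("qvalue" %in% names(df)) df$qvalue else NULL,
                     q_floor = q_floor, log_base = log_base)
}

#' Classify genes as up / down / unchanged by FDR and fold-change sign
#'
#' Strict threshold: a gene is differentially expressed when `q < q_threshold`
#' (q exactly at the threshold counts as unchanged); direction follows the
#' sign of log2fc. The three classes partition the gene universe.
#'
#' @param records data.frame with columns `gene_id`, `log2fc`, `qvalue`.
#' @param q_threshold FDR cutoff (default 0.05).
#' @return list with character vectors `up`, `down`, `noc`.
#' @export
classify_genes <- function(records, q_threshold = 0.05) {
  if (anyDuplicated(records$gene_id)) stop("duplicate gene ids")
  sig <- records$qvalue < q_threshold
  up <- records$gene_id[sig & records$log2fc > 0]
  down <- records$gene_id[sig & records$log2fc < 0]
  list(up = up, down = down,
       noc = setdiff(records$gene_id, c(up, down)))
}

#' Log2 enrichment of the overlap of two gene sets
#'
#' Enrichment of the observed overlap over the value expected if the two sets
#' were drawn independently from the universe:
#' `log2( (|A n B| / N) / ((|A|/N) * (|B|/N)) )`, with a hypergeometric
#' upper-tail p-value for an overlap at least as large as observed.
#'
#' @param setA,setB character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all gene ids considered.
#' @return list with `log2_enrichment`, `p`, and the overlap size `k`.
#' @export
set_log2_enrichment <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(setA) == 0L || length(setB) == 0L) stop("empty gene set")
  if (!all(setA %in% universe) || !all(setB %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  N <- length(unique(universe))
  a <- length(unique(setA)); b <- length(unique(setB))
  k <- length(intersect(setA, setB))
  enr <- log2((k / N) / ((a / N) * (b / N)))
  p <- stats::phyper(k - 1L, a, N - a, b, lower.tail = FALSE)
  list(log2_enrichment = enr, p = p, k = k)
}
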