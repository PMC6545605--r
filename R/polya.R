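#' Map a 3' RACE clone end to a polyA-site position
#'
#' Positions are numbered relative to the stop codon: 1 is the first base
#' downstream of the last base of the stop codon, 0 a clone ending exactly
#' at the stop codon's last base.  On the `+` strand
#' `rel_pos = clone_last_base - stop_last_base`; on the `-` strand the
#' mirror `stop_last_base - clone_last_base`.  Negative values (clone ends
#' inside the CDS) are returned as-is so callers can flag them.
#'
#' @param clone_last_base genomic coordinate(s) of the last templated
#'   nucleotide before the polyA tail.
#' @param stop_last_base genomic coordinate of the stop codon's last base.
#' @param strand `"+"` or `"-"` (recycled).
#' @return integer vector of relative positions.
#' @export
map_polya_site <- function(clone_last_base, stop_last_base, strand) {
  .check_strand(strand)
  n <- max(length(clone_last_base), length(stop_last_base), length(strand))
  clone_last_base <- rep_len(clone_last_base, n)
  stop_last_base <- rep_len(stop_last_base, n)
  strand <- rep_len(strand, n)
  out <- ifelse(strand == "+",
                clone_last_base - stop_last_base,
                stop_last_base - clone_last_base)
  as.integer(out)
}

#' Tally polyA-site usage from clone positions
#'
#' With `cluster_window = 0` (the default) the tally is exact per position.
#' With a positive window, positions are merged greedily onto modal
#' positions: repeatedly, the position with the most clones (ties to the
#' smallest position) absorbs all positions within `cluster_window` bp.
#' Total clone count is conserved for any window.
#'
#' @param rel_positions integer vector of relative polyA positions.
#' @param cluster_window merge radius in bp (default 0 = exact tally).
#' @return data.frame with columns `rel_pos`, `clone_count`, sorted by
#'   position.
#' @export
tally_sites <- function(rel_positions, cluster_window = 0L) {
  if (!length(rel_positions)) {
    return(data.frame(rel_pos = integer(), clone_count = integer()))
  }
  tab <- table(as.integer(rel_positions))
  pos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  if (cluster_window > 0) {
    out_pos <- integer(); out_cnt <- integer()
    while (length(pos)) {
      m <- which(cnt == max(cnt))
      m <- m[which.min(pos[m])]          # ties: smallest position
      members <- abs(pos - pos[m]) <= cluster_window
      out_pos <- c(out_pos, pos[m])
      out_cnt <- c(out_cnt, sum(cnt[members]))
      pos <- pos[!members]; cnt <- cnt[!members]
    }
    o <- order(out_pos)
    return(data.frame(rel_pos = out_pos[o], clone_count = out_cnt[o]))
  }
  data.frame(rel_pos = pos, clone_count = cnt)
}

#' Relative transcript level by the ddCt method
#'
#' `2^-ddCt` with `ddCt = (Ct_target,cond - Ct_ref,cond) -
#' (Ct_target,ctrl - Ct_ref,ctrl)`; the reference gene (e.g., actin)
#' normalizes within condition and the control condition anchors the fold
#' change.
#'
#' @param ct_target_cond,ct_ref_cond Ct values in the condition of
#'   interest.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control condition.
#' @return list with elements `value` (the fold change) and `components`.
#' @export
ddct_fold <- function(ct_target_cond, ct_ref_cond, ct_target_ctrl,
                      ct_ref_ctrl) {
  comp <- c(ct_target_cond = ct_target_cond, ct_ref_cond = ct_ref_cond,
            ct_target_ctrl = ct_target_ctrl, ct_ref_ctrl = ct_ref_ctrl)
  if (any(!is.finite(comp))) .stopf("all Ct values must be finite")
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  list(value = 2^(-ddct), components = comp)
}

#' m6A-IP enrichment score
#'
#' Target abundance is first normalized against an internal control (e.g.,
#' TUB2) within the immunoprecipitated and input fractions, then the IP
#' value is normalized against the input:
#' `(ip_target / ip_ref) / (input_target / input_ref)`.  Invariant under
#' rescaling all four abundances by a common factor.
#'
#' @param ip_target,ip_ref abundances in the immunoprecipitated fraction.
#' @param input_target,input_ref abundances in the input fraction.
#' @return list with elements `value` and `components`.
#' @export
m6a_enrichment <- function(ip_target, ip_ref, input_target, input_ref) {
  comp <- c(ip_target = ip_target, ip_ref = ip_ref,
            input_target = input_target, input_ref = input_ref)
  if (any(!is.finite(comp)) || any(comp <= 0)) {
    .stopf("all abundances must be positive")
  }
  list(value = (ip_target / ip_ref) / (input_target / input_ref),
       components = comp)
}

#' Read a clone-end position table and tally polyA sites per gene
#'
#' @param path TSV with columns `gene_id`, `clone_last_base`; stop-codon
#'   coordinates and strands come from `stops`.
#' @param stops data.frame with columns `gene_id`, `stop_last_base`,
#'   `strand`.
#' @param cluster_window see [tally_sites()].
#' @return data.frame with columns `gene_id`, `rel_pos`, `clone_count`,
#'   `inside_cds` (TRUE when `rel_pos < 0`).
#' @export
polya_histogram <- function(path, stops, cluster_window = 0L) {
  if (!file.exists(path)) .stopf("clone table not found: %s", path)
  clones <- read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "clone_last_base") %in% names(clones)),
            all(c("gene_id", "stop_last_base", "strand") %in% names(stops)))
  out <- lapply(unique(clones$gene_id), function(g) {
    st <- stops[stops$gene_id == g, , drop = FALSE]
    if (!nrow(st)) .stopf("no stop-codon record for gene %s", g)
    rel <- map_polya_site(clones$clone_last_base[clones$gene_id == g],
                          st$stop_last_base[1L], st$strand[1L])
    cbind(gene_id = g, tally_sites(rel, cluster_window))
  })
  res <- do.call(rbind, out)
  res$inside_cds <- res$rel_pos < 0
  res
}
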