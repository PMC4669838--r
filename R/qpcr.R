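#' Validate a qPCR Ct table
#'
#' A Ct table has one row per well: columns `sample`, `group`, `gene`,
#' `replicate`, `ct`, all Ct values positive.
#'
#' @param ct_table Data frame.
#' @return `ct_table`, invisibly; errors on violation.
#' @export
validate_ct_table <- function(ct_table) {
  req <- c("sample", "group", "gene", "replicate", "ct")
  if (!is.data.frame(ct_table) || !all(req %in% names(ct_table)))
    stop("a Ct table needs columns sample, group, gene, replicate, ct")
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0))
    stop("all Ct values must be positive and finite")
  invisible(ct_table)
}

#' Delta-Ct: reference-gene normalization
#'
#' The difference in cycle thresholds between a target gene and the
#' housekeeping reference measured in the same well set:
#' delta-Ct = Ct(target) - Ct(reference). A higher delta-Ct means less
#' target template.
#'
#' @param ct_target,ct_reference Numeric Ct values (cycles), recycled as
#'   usual.
#' @return Numeric delta-Ct in cycles.
#' @export
#' @examples
#' delta_ct(25, 20)
delta_ct <- function(ct_target, ct_reference) {
  stopifnot(is.numeric(ct_target), is.numeric(ct_reference))
  ct_target - ct_reference
}

#' Per-replicate delta-Ct for a whole Ct table
#'
#' Normalizes every target-gene well against the reference-gene well of the
#' same sample and replicate, preserving replicate-level variance for the
#' downstream tests.
#'
#' @param ct_table Ct table (see [validate_ct_table()]).
#' @param reference_gene Housekeeping gene (default "HPRT").
#' @return Data frame sample, group, gene, replicate, delta_ct (reference
#'   gene rows are dropped).
#' @export
delta_ct_table <- function(ct_table, reference_gene = "HPRT") {
  validate_ct_table(ct_table)
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (!nrow(ref))
    stop(sprintf("reference gene '%s' absent from the Ct table",
                 reference_gene))
  tgt <- ct_table[ct_table$gene != reference_gene, ]
  key <- function(d) paste(d$sample, d$replicate)
  ref_ct <- setNames(ref$ct, key(ref))
  miss <- !(key(tgt) %in% names(ref_ct))
  if (any(miss))
    stop(sprintf("sample '%s' (replicate %s) has no reference-gene Ct",
                 tgt$sample[miss][1], tgt$replicate[miss][1]), call. = FALSE)
  data.frame(sample = tgt$sample, group = tgt$group, gene = tgt$gene,
             replicate = tgt$replicate,
             delta_ct = delta_ct(tgt$ct, as.numeric(ref_ct[key(tgt)])),
             stringsAsFactors = FALSE)
}

#' Fold change from two groups of delta-Ct replicates
#'
#' delta-delta-Ct = mean delta-Ct(treated) - mean delta-Ct(control);
#' relative expression fold = 2^(-delta-delta-Ct). Swapping the groups
#' inverts the fold exactly. When both groups have >= 2 replicates a
#' two-sided t-test on the delta-Ct values is attached.
#'
#' @param dct_treated,dct_control Numeric vectors of per-replicate
#'   delta-Ct values.
#' @param var_equal Pooled-variance t-test (default TRUE; FALSE = Welch).
#' @return List with `delta_delta_ct`, `fold`, group means/sds/ns and
#'   `p_value` (NA when untestable).
#' @export
#' @examples
#' fold_change(c(4.0, 4.1), c(5.0, 5.1))$fold # ~2-fold up
fold_change <- function(dct_treated, dct_control, var_equal = TRUE) {
  stopifnot(length(dct_treated) >= 1, length(dct_control) >= 1)
  ddct <- mean(dct_treated) - mean(dct_control)
  p <- if (length(dct_treated) >= 2 && length(dct_control) >= 2)
    t.test(dct_treated, dct_control, var.equal = var_equal)$p.value
  else NA_real_
  list(delta_delta_ct = ddct, fold = 2^(-ddct),
       mean_treated = mean(dct_treated), sd_treated = sd(dct_treated),
       n_treated = length(dct_treated),
       mean_control = mean(dct_control), sd_control = sd(dct_control),
       n_control = length(dct_control), p_value = p)
}

#' Per-gene fold changes between two groups of a Ct table
#'
#' @param ct_table Ct table.
#' @param treated,control Group labels (treated vs reference/control).
#' @param reference_gene Housekeeping gene (default "HPRT").
#' @param var_equal Pooled-variance t-test flag.
#' @return Data frame, one row per target gene: gene, n per group, group
#'   delta-Ct mean and sd, delta_delta_ct, fold, p_value.
#' @export
fold_change_table <- function(ct_table, treated, control,
                              reference_gene = "HPRT", var_equal = TRUE) {
  dct <- delta_ct_table(ct_table, reference_gene)
  if (!all(c(treated, control) %in% dct$group))
    stop("treated/control groups absent from the Ct table")
  genes <- unique(dct$gene)
  rows <- lapply(genes, function(gn) {
    t_v <- dct$delta_ct[dct$gene == gn & dct$group == treated]
    c_v <- dct$delta_ct[dct$gene == gn & dct$group == control]
    fc <- fold_change(t_v, c_v, var_equal)
    data.frame(gene = gn, n_treated = fc$n_treated,
               n_control = fc$n_control,
               delta_ct_treated = fc$mean_treated,
               sd_treated = fc$sd_treated,
               delta_ct_control = fc$mean_control,
               sd_control = fc$sd_control,
               delta_delta_ct = fc$delta_delta_ct, fold = fc$fold,
               p_value = fc$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group comparison of delta-Ct values
#'
#' Two groups: two-sided Student's t-test on delta-Ct (pooled variance by
#' default). More than two: one-way ANOVA; when the omnibus test is
#' significant at `alpha`, Bonferroni-adjusted pairwise t-tests (pooled SD)
#' follow as the post-hoc step.
#'
#' @param ct_table Ct table.
#' @param reference_gene Housekeeping gene.
#' @param var_equal Pooled-variance flag for the two-group test.
#' @param alpha Significance level gating the post-hoc step (default 0.05).
#' @return List with `per_gene` (gene, test, p_value) and `pairwise`
#'   (gene, group1, group2, p_adjusted; NULL when no post-hoc ran).
#' @export
compare_groups <- function(ct_table, reference_gene = "HPRT",
                           var_equal = TRUE, alpha = 0.05) {
  dct <- delta_ct_table(ct_table, reference_gene)
  groups <- unique(dct$group)
  if (length(groups) < 2) stop("need at least two groups")
  tab <- table(dct$gene, dct$group)
  if (any(tab < 2)) stop("every gene needs >= 2 replicates per group")
  genes <- unique(dct$gene)
  per_gene <- vector("list", length(genes))
  pairwise <- list()
  for (i in seq_along(genes)) {
    d <- dct[dct$gene == genes[i], ]
    if (length(groups) == 2) {
      p <- t.test(delta_ct ~ group, data = d, var.equal = var_equal)$p.value
      per_gene[[i]] <- data.frame(gene = genes[i], test = "t",
                                  p_value = p, stringsAsFactors = FALSE)
    } else {
      fit <- aov(delta_ct ~ group, data = d)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      per_gene[[i]] <- data.frame(gene = genes[i], test = "anova",
                                  p_value = p, stringsAsFactors = FALSE)
      if (is.finite(p) && p < alpha) {
        pw <- pairwise.t.test(d$delta_ct, d$group,
                              p.adjust.method = "bonferroni", pool.sd = TRUE)
        m <- pw$p.value
        idx <- which(!is.na(m), arr.ind = TRUE)
        pairwise[[length(pairwise) + 1L]] <- data.frame(
          gene = genes[i], group1 = rownames(m)[idx[, 1]],
          group2 = colnames(m)[idx[, 2]], p_adjusted = m[idx],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(per_gene = do.call(rbind, per_gene),
       pairwise = if (length(pairwise)) do.call(rbind, pairwise) else NULL)
}

#' Methylation-expression concordance report
#'
#' Scores each gene for agreement between its promoter methylation change
#' and its expression change: promoter hypomethylation with upregulation
#' (fold > 1), or hypermethylation with downregulation (fold < 1), is
#' concordant. Genes with unchanged or mixed promoter status, a fold of
#' exactly 1, or present in only one input are left unscored.
#'
#' @param fold_changes Data frame with columns `gene`, `fold` (e.g. from
#'   [fold_change_table()]).
#' @param promoter_statuses Data frame with columns `gene`, `status` (from
#'   [promoter_methylation_status()]).
#' @return Data frame gene, status, fold, direction, scored, concordant,
#'   with attribute `concordant_fraction` (among scored genes).
#' @export
concordance_report <- function(fold_changes, promoter_statuses) {
  stopifnot(all(c("gene", "fold") %in% names(fold_changes)),
            all(c("gene", "status") %in% names(promoter_statuses)))
  genes <- union(fold_changes$gene, promoter_statuses$gene)
  fold <- fold_changes$fold[match(genes, fold_changes$gene)]
  status <- promoter_statuses$status[match(genes, promoter_statuses$gene)]
  direction <- ifelse(is.na(fold), NA_character_,
                      ifelse(fold > 1, "up", ifelse(fold < 1, "down", "flat")))
  hypo <- !is.na(status) & startsWith(status, "hypomethylated")
  hyper <- !is.na(status) & startsWith(status, "hypermethylated")
  scored <- (hypo | hyper) & !is.na(direction) & direction != "flat"
  concordant <- rep(NA, length(genes))
  concordant[scored] <- (hypo[scored] & direction[scored] == "up") |
    (hyper[scored] & direction[scored] == "down")
  out <- data.frame(gene = genes, status = status, fold = fold,
                    direction = direction, scored = scored,
                    concordant = concordant, stringsAsFactors = FALSE)
  attr(out, "concordant_fraction") <-
    if (any(scored)) mean(concordant[scored]) else NA_real_
  out
}
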