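# Shared builders for summary-data fixtures.

# Minimal harmonized set (class mr_harmonized) from raw arrays.
hset_df <- function(bx, sx, by, sy, eaf = rep(0.5, length(bx)),
                    p_out = rep(0.5, length(bx)),
                    n_exp = rep(437354, length(bx)),
                    n_out = rep(311635, length(bx)),
                    snp_id = sprintf("snp%03d", seq_along(bx))) {
  h <- data.frame(snp_id = snp_id, chrom = "1", pos = seq_along(bx) * 1e6,
                  effect_allele = "A", other_allele = "G",
                  eaf = eaf, beta_exp = bx, se_exp = sx,
                  p_exp = 2 * pnorm(-abs(bx / sx)), n_exp = n_exp,
                  beta_out = by, se_out = sy, p_out = p_out, n_out = n_out,
                  eaf_out = eaf, flipped = FALSE, palindromic = FALSE,
                  excluded_reason = NA_character_,
                  stringsAsFactors = FALSE)
  class(h) <- c("mr_harmonized", "data.frame")
  h
}

# GWAS record table from explicit fields.
records_df <- function(snp_id, beta, se, eaf = rep(0.5, length(snp_id)),
                       ea = rep("A", length(snp_id)),
                       oa = rep("G", length(snp_id)),
                       chrom = rep("1", length(snp_id)),
                       pos = seq_along(snp_id) * 1e6,
                       n = rep(437354, length(snp_id))) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = 2 * pnorm(-abs(beta / se)),
             n = n, stringsAsFactors = FALSE)
}

# Keep only genome-wide-significant instruments of a simulated array set,
# mirroring the pipeline's selection step.
select_arrays <- function(a, p = 5e-8) {
  keep <- 2 * pnorm(-abs(a$bx / a$sx)) < p & a$bx > 0
  out <- lapply(a[c("bx", "sx", "by", "sy")], `[`, keep)
  out$snp_id <- a$snp_id[keep]
  out
}

quant_meta <- function(n = 437354, label = "exposure")
  study_meta(label, "quantitative", n = n)

binary_meta <- function(n = 311635, n_cases = 39818, label = "outcome")
  study_meta(label, "binary", n = n, n_cases = n_cases)

write_gwas_tsv <- function(df, path, headers = NULL) {
  canonical <- c(snp_id = "SNP", chrom = "CHR", pos = "POS",
                 effect_allele = "EA", other_allele = "OA", eaf = "EAF",
                 beta = "BETA", se = "SE", pvalue = "P", n = "N",
                 n_cases = "N_CASES", n_controls = "N_CONTROLS")
  if (is.null(headers)) headers <- canonical
  out <- df
  names(out) <- headers[names(df)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
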