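# Shared fixture builders; everything is generated in code, nothing stored.

# Two-side tumour/immune population over a toy transcriptome whose gene ids
# are remapped so marker-bearing genes exist (CD3D, CD68, EPCAM, VIM, ...).
marker_gene_ids <- function(n_other = 20) {
  c("CD3D", "CD68", "EPCAM", "CDH1", "VIM", "ACTA2", "FN1", "ZEB1",
    "THY1", "CD44", "FADS2", "CCL4",
    sprintf("OTHER%03d", seq_len(n_other)))
}

two_side_spec <- function(genes = marker_gene_ids(), doublet_rate = 0,
                          frags_per_gene = 6) {
  classes <- data.frame(
    name = c("cancer_E", "cancer_M", "T_E", "T_M", "mac_E", "mac_M"),
    class = rep(c("cancer", "T_cell", "macrophage"), each = 2),
    side = rep(c("E", "M"), 3),
    species = "HUMAN",
    prop = c(0.3, 0.2, 0.1, 0.2, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
  P <- matrix(0.05, nrow = nrow(classes), ncol = length(genes),
              dimnames = list(classes$name, genes))
  P[, "CD3D"] <- c(0, 0, 0.95, 0.95, 0, 0)
  P[, "CD68"] <- c(0, 0, 0, 0, 0.95, 0.95)
  P[c("cancer_E", "cancer_M"), "EPCAM"] <- 0.7
  P[c("cancer_E", "cancer_M"), "CDH1"] <- 0.4
  P[c("cancer_E", "cancer_M"), "VIM"] <- c(0.5, 0.3)
  P[c("cancer_E", "cancer_M"), "ZEB1"] <- 0.2
  # side-differential gene mirroring a signature-table row (48% vs 31%)
  P[c("cancer_E", "cancer_M"), "FADS2"] <- c(0.48, 0.31)
  P[c("T_E", "T_M"), "CCL4"] <- c(0.10, 0.30)
  population_spec(genes, classes, positivity = P, base_positivity = 0.05,
                  frags_per_gene = frags_per_gene, doublet_rate = doublet_rate)
}

default_rules <- function() {
  marker_rules(
    class_rules = list(T_cell = "CD3D", macrophage = "CD68",
                       cancer = c("EPCAM", "CDH1", "VIM")),
    priority = c("T_cell", "macrophage", "cancer"),
    positivity_threshold = 1
  )
}

# expand a matrix to given row/col universe, zero-filling
align_counts <- function(m, row_names, col_names) {
  m <- as.matrix(m)
  out <- matrix(0, length(row_names), length(col_names),
                dimnames = list(row_names, col_names))
  out[rownames(m), colnames(m)] <- m
  out
}

# barnyard population: two species, balanced, species-exclusive expression
barnyard_spec <- function(tx, doublet_rate = 0) {
  sp <- unique(tx$species)
  classes <- data.frame(name = sp, class = "cell", side = "A", species = sp,
                        prop = rep(1 / length(sp), length(sp)),
                        stringsAsFactors = FALSE)
  P <- matrix(0, nrow = length(sp), ncol = nrow(tx),
              dimnames = list(sp, tx$gene_id))
  for (s in sp) P[s, tx$species == s] <- 0.5
  population_spec(tx$gene_id, classes, positivity = P, base_positivity = 0,
                  frags_per_gene = 4, doublet_rate = doublet_rate)
}
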