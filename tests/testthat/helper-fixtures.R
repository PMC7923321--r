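# Small fixtures built in code; no stored data files.

# 3 genes x 2 samples expression TSV; returns the path
tiny_expr_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  writeLines(c("gene\tCELL1\tCELL2",
               "PTGR1\t5.25\t8.5",
               "GENE2\t7\t7.125",
               "GENE3\t4.5\t6.75"),
             path)
  path
}

tiny_sens_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                           ic50 = c(1e-7, 14.3e-9)) {
  path <- file.path(dir, "sens.tsv")
  writeLines(c("sample_id\tic50_molar\ttumor_type\tlineage",
               sprintf("CELL1\t%.10g\tovarian\tsolid", ic50[1]),
               sprintf("CELL2\t%.10g\tbreast\tsolid", ic50[2])),
             path)
  path
}

# compact generator config for fast module tests
small_config <- function(seed = 1L, n_train = 40L, n_blind = 20L,
                         n_genes = 150L, ...) {
  generator_config(n_train = n_train, n_blind = n_blind, n_genes = n_genes,
                   seed = seed, ...)
}

# sample x gene matrix of independent standard normals with gene names
noise_matrix <- function(n, p, prefix = "N") {
  m <- matrix(stats::rnorm(n * p), n, p)
  colnames(m) <- sprintf("%s%03d", prefix, seq_len(p))
  m
}
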