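# Independent oracles used by the genetics tests.  These deliberately avoid
# enumerate_gametes()/cross_distribution(): offspring distributions are
# rebuilt by brute-force iteration over every parental allele choice.

# every constructible genotype (all unordered allele pairs at each locus,
# both karyotypes)
all_genotypes <- function() {
  pair_set <- function(alleles) {
    list(c(alleles[1], alleles[1]), c(alleles[1], alleles[2]),
         c(alleles[2], alleles[2]))
  }
  xs_f <- pair_set(c("FL", "+"))
  pyr <- pair_set(c("res", "wt"))
  pta <- pair_set(c("PTA", "+"))
  ridl <- pair_set(c("RIDL", "+"))
  out <- list()
  for (p1 in pyr) for (p2 in pta) for (p3 in ridl) {
    for (x in xs_f)
      out[[length(out) + 1L]] <- genotype("XX", x, p1, p2, p3)
    for (x in c("FL", "+"))
      out[[length(out) + 1L]] <- genotype("XY", x, p1, p2, p3)
  }
  out
}

# brute-force cross: iterate over each parent's two allele copies at every
# locus (and the sperm sex chromosome), weight every combination equally
oracle_cross <- function(mother, father) {
  acc <- new.env(parent = emptyenv())
  add <- function(code, p) {
    acc[[code]] <- (if (is.null(acc[[code]])) 0 else acc[[code]]) + p
  }
  m <- mother; f <- father
  for (mx in 1:2) for (mp in 1:2) for (mt in 1:2) for (mr in 1:2)
    for (sperm_sex in 1:2) for (fp in 1:2) for (ft in 1:2) for (fr in 1:2) {
      p <- (1 / 2)^8
      pyr <- c(m$pyr[mp], f$pyr[fp])
      pta <- c(m$pta[mt], f$pta[ft])
      ridl <- c(m$ridl[mr], f$ridl[fr])
      z <- if (sperm_sex == 1L) {
        genotype("XX", c(m$x[mx], f$x[1]), pyr, pta, ridl)
      } else {
        genotype("XY", m$x[mx], pyr, pta, ridl)
      }
      add(format(z), p)
    }
  codes <- sort(ls(acc))
  data.frame(genotype = codes,
             probability = vapply(codes, function(k) acc[[k]], numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# brute-force EGI rule: count allele copies explicitly
oracle_egi <- function(g) {
  n_pta <- sum(g$pta == "PTA")
  n_res <- sum(g$pyr == "res")
  if (n_pta >= 1 && n_res < 2) FALSE else TRUE
}

strain_templates <- c("WT", "SSIMS", "EGI", "FL", "RIDL")
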