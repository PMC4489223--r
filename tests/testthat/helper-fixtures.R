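# Small constructed inputs shared across test files.

# minimal PDB text: full backbone for a run of residues along x
tiny_pdb_text <- function(n = 3, chain = "A", res_names = rep("ALA", n),
                          start_res = 1L) {
  lines <- character(0)
  serial <- 0L
  for (k in seq_len(n)) {
    x0 <- (k - 1) * 3.8
    at <- rbind(c("N", x0 - 0.7, 1.0, 0.2), c("CA", x0, 0, 0),
                c("C", x0 + 0.8, 1.0, -0.2), c("O", x0 + 0.8, 2.2, -0.2))
    for (a in seq_len(4)) {
      serial <- serial + 1L
      nm <- at[a, 1]
      name4 <- formatC(paste0(" ", nm), width = -4)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
        serial, name4, res_names[k], chain, start_res + k - 1L,
        as.numeric(at[a, 2]), as.numeric(at[a, 3]), as.numeric(at[a, 4]),
        substr(nm, 1, 1)))
    }
  }
  c(lines, "TER", "END")
}

# bare straight-ish cg peptide chain used where geometry is irrelevant
toy_peptide_chain <- function(sequence = "AAAAA") {
  n <- nchar(sequence)
  t <- (seq_len(n) - 1) * 3.8 * cos(15 * pi / 180)
  o <- ifelse(seq_len(n) %% 2 == 0, 3.8 * sin(15 * pi / 180), 0)
  ca <- cbind(o, 0, t)
  cg_chain(ca, pepdock:::.sc_from_ca(ca, sequence), sequence,
           chain_id = rep("P", n))
}

toy_receptor_chain <- function(n = 10) {
  build_cg(ideal_helix(n))
}

random_complex <- function(seq_r = "ADEFGHIKLM", seq_p = "FKW",
                           sep = 6) {
  nr <- nchar(seq_r)
  ca_r <- matrix(stats::rnorm(nr * 3, sd = 4), nr, 3)
  # rescale consecutive distances to ~3.8 so cg_chain() accepts it
  for (i in 2:nr) {
    d <- ca_r[i, ] - ca_r[i - 1, ]
    ca_r[i, ] <- ca_r[i - 1, ] + 3.8 * d / sqrt(sum(d^2))
  }
  rec <- cg_chain(ca_r, pepdock:::.sc_from_ca(ca_r, seq_r), seq_r)
  pep0 <- random_peptide_conformation(validate_peptide(seq_p))
  pep <- pep0
  shift <- colMeans(rec$ca) + c(sep, 0, 0) - colMeans(pep0$ca)
  pep$ca <- sweep(pep0$ca, 2, shift, `+`)
  pep$sc <- sweep(pep0$sc, 2, shift, `+`)
  cg_complex(rec, pep)
}
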