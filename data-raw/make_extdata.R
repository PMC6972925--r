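# One-off generator for packaged structural tables and motif PFMs.
# Run from repo root: Rscript scratch/make_extdata.R

revcomp <- function(s) chartr("ACGT", "TGCA", sapply(strsplit(s, ""), function(x) paste(rev(x), collapse = "")))

expand_sym <- function(vals) {
  # vals: named vector on canonical k-mers; mirror onto reverse complements
  out <- vals
  for (km in names(vals)) out[revcomp(km)] <- vals[[km]]
  k <- nchar(names(vals)[1])
  all <- apply(expand.grid(rep(list(c("A","C","G","T")), k))[, k:1, drop = FALSE],
               1, paste, collapse = "")
  stopifnot(setequal(names(out), all))
  out[sort(all)]
}

di_keys <- c("AA","AC","AG","AT","CA","CC","CG","GA","GC","TA")
di <- list(
  stacking_energy       = c(-5.37,-10.51,-6.78,-6.57,-6.57,-8.26,-9.69,-9.81,-14.59,-3.82),
  propeller_twist       = c(-18.66,-13.10,-14.00,-15.01,-9.45,-8.11,-10.03,-13.48,-11.08,-11.85),
  duplex_free_energy    = c(-1.00,-1.44,-1.28,-0.88,-1.45,-1.84,-2.17,-1.30,-2.24,-0.58),
  duplex_disrupt_energy = c(1.9,1.3,1.6,1.5,1.9,3.1,3.6,1.6,3.1,0.9),
  denaturation          = c(54.50,97.73,58.42,57.02,54.71,85.97,72.55,86.44,136.12,36.73),
  bending_stiffness     = c(35,60,60,20,60,130,85,60,85,20),
  z_dna                 = c(3.9,4.6,3.4,5.9,1.3,2.4,0.7,3.4,4.0,2.5),
  a_philicity           = c(0.10,1.30,0.80,0.00,0.70,1.10,1.60,1.10,2.00,-0.20),
  protein_deformation   = c(2.9,2.3,2.1,1.6,9.8,6.1,12.1,4.5,4.0,6.3),
  b_dna_twist           = c(35.1,31.5,31.9,29.3,37.3,32.9,36.1,36.3,33.6,37.8),
  protein_dna_twist     = c(35.3,32.6,33.4,30.5,36.6,33.7,35.4,35.8,34.4,40.0)
)

tri_keys <- c("AAA","AAC","AAG","AAT","ACA","ACC","ACG","ACT","AGA","AGC","AGG",
              "ATA","ATC","ATG","CAA","CAC","CAG","CCA","CCC","CCG","CGA","CGC",
              "CTA","CTC","GAA","GAC","GCA","GCC","GGA","GTA","TAA","TCA")
tri <- list(
  bendability = c(-0.274,-0.205,-0.081,-0.280,-0.006,-0.032,-0.033,-0.183,0.027,
                  0.017,-0.057,0.182,-0.110,0.134,0.015,0.040,0.175,-0.246,-0.012,
                  -0.136,-0.003,-0.077,0.090,0.031,-0.037,-0.013,0.076,0.107,0.013,
                  0.025,0.068,0.194),
  nucleosome_positioning = c(-0.36,-0.06,0.06,-0.30,0.06,0.08,0.08,0.11,-0.09,0.25,
                             0.08,-0.13,0.07,0.18,-0.09,0.17,-0.02,0.08,0.13,0.02,
                             0.31,0.25,-0.18,0.08,-0.12,0.08,0.13,0.45,-0.05,-0.06,
                             -0.20,0.08)
)

dir.create("inst/extdata/structural", recursive = TRUE, showWarnings = FALSE)
write_table <- function(name, keys, vals) {
  v <- stats::setNames(vals, keys)
  full <- expand_sym(v)
  con <- file(file.path("inst/extdata/structural", paste0(name, ".tsv")), "w")
  writeLines(paste(name, nchar(keys[1]), sep = "\t"), con)
  writeLines(paste(names(full), format(unname(full), trim = TRUE), sep = "\t"), con)
  close(con)
}
for (nm in names(di)) write_table(nm, di_keys, di[[nm]])
for (nm in names(tri)) write_table(nm, tri_keys, tri[[nm]])

# ---- motif PFMs from IUPAC consensus --------------------------------------
iupac <- list(A="A", C="C", G="G", T="T", R=c("A","G"), Y=c("C","T"),
              S=c("C","G"), W=c("A","T"), K=c("G","T"), M=c("A","C"),
              B=c("C","G","T"), D=c("A","G","T"), H=c("A","C","T"),
              V=c("A","C","G"), N=c("A","C","G","T"))
consensus <- c(
  Inr         = "YYANWYY",
  `TATA-box`  = "TATAWAAR",
  MTE         = "CSARCSSAACGS",
  `GC-Box`    = "GGGGCGGGG",
  `CCAAT-Box` = "RRCCAATSA",
  DPE         = "RGWYVT",
  BREu        = "SSRCGCC",
  BREd        = "RTDKKKK",
  `DCE-S-I`   = "CTTC",
  `DCE-S-II`  = "CTGT",
  `DCE-S-III` = "AGC",
  XCPE1       = "DSGYGGRASM",
  MED1        = "GCTCCS"
)
pfm_lines <- character(0)
for (i in seq_along(consensus)) {
  id <- names(consensus)[i]
  letters <- strsplit(consensus[[i]], "")[[1]]
  counts <- matrix(0L, 4, length(letters), dimnames = list(c("A","C","G","T"), NULL))
  for (j in seq_along(letters)) {
    allowed <- iupac[[letters[j]]]
    counts[, j] <- 2L                       # background
    counts[allowed, j] <- counts[allowed, j] + as.integer(round(92 / length(allowed)))
  }
  pfm_lines <- c(pfm_lines, sprintf(">SYN%04d %s", i, id))
  for (b in c("A","C","G","T"))
    pfm_lines <- c(pfm_lines, sprintf("%s  [ %s ]", b, paste(sprintf("%3d", counts[b, ]), collapse = " ")))
}
writeLines(pfm_lines, "inst/extdata/motifs/pol2_core_motifs_synthetic.jaspar")
cat("wrote", length(di) + length(tri), "tables and", length(consensus), "motifs\n")
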