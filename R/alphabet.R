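# Integer alphabet shared with the C++ index layer:
# 0 = sentinel '$', 1 = record separator '#', 2 = A, 3 = C, 4 = G, 5 = N, 6 = T

.CODE_SENTINEL <- 0L
.CODE_SEP <- 1L
.CODE_N <- 5L
.DNA_CHARS <- c("$", "#", "A", "C", "G", "N", "T")

.dna_code_table <- local({
  tab <- rep(.CODE_N, 128L)
  tab[utf8ToInt("A")] <- 2L; tab[utf8ToInt("a")] <- 2L
  tab[utf8ToInt("C")] <- 3L; tab[utf8ToInt("c")] <- 3L
  tab[utf8ToInt("G")] <- 4L; tab[utf8ToInt("g")] <- 4L
  tab[utf8ToInt("T")] <- 6L; tab[utf8ToInt("t")] <- 6L
  tab[utf8ToInt("$")] <- .CODE_SENTINEL
  tab[utf8ToInt("#")] <- .CODE_SEP
  tab
})

# Encode one DNA string to integer codes; anything outside ACGT maps to N.
encode_dna <- function(x) {
  stopifnot(length(x) == 1L)
  .dna_code_table[utf8ToInt(x)]
}

decode_dna <- function(codes) {
  paste(.DNA_CHARS[codes + 1L], collapse = "")
}

# Uppercase and collapse every non-ACGT character to N.
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# Vectorized reverse complement on plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
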