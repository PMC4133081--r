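# nucleotide / protein alphabets used by the validators
NT_LETTERS <- c("A", "C", "G", "T", "N")
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_LETTERS_X <- c(AA_LETTERS, "X")

`%||%` <- function(a, b) if (is.null(a)) b else a
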