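# Internal IUPAC alphabet tables shared by the i/o and distance code.
#
# Integer codes: 1..4 = A,C,G,T; 5..14 = two/three-base ambiguity codes;
# 15 = missing ('N', '?', 'X'); 16 = gap ('-').  'U' folds into 'T' so
# RNA-style input is tolerated.  Only '-' counts as a gap; N/?/X are all
# "missing" and, like gaps, excluded from pairwise comparison.

.fb_alphabet <- c(
  A = 1L, C = 2L, G = 3L, T = 4L, U = 4L,
  M = 5L, R = 6L, W = 7L, S = 8L, Y = 9L, K = 10L,
  V = 11L, H = 12L, D = 13L, B = 14L,
  N = 15L, `?` = 15L, X = 15L, `-` = 16L
)

.fb_code_chars <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                    "V", "H", "D", "B", "?", "-")

.fb_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T")
)

# Pairwise lookup tables, flattened so that a column with codes (a, b) is
# addressed as (a - 1) * 16 + b.  `weight` is the expected mismatch under
# uniform independent resolution of the two codes over their compatible
# unambiguous states: 1 - |matches| / (|set_a| * |set_b|).
.fb_pair <- local({
  n <- 16L
  comparable <- matrix(FALSE, n, n)
  comparable[1:14, 1:14] <- TRUE
  weight <- matrix(0, n, n)
  for (i in 1:14) {
    for (j in 1:14) {
      si <- .fb_sets[[i]]
      sj <- .fb_sets[[j]]
      weight[i, j] <- 1 - length(intersect(si, sj)) /
        (length(si) * length(sj))
    }
  }
  ts <- matrix(FALSE, n, n)                      # A<->G, C<->T
  ts[1, 3] <- ts[3, 1] <- ts[2, 4] <- ts[4, 2] <- TRUE
  unamb <- matrix(FALSE, n, n)
  unamb[1:4, 1:4] <- TRUE
  tv <- unamb & weight > 0 & !ts
  ambig <- comparable & !unamb                   # at least one ambiguity code
  list(
    comparable = as.vector(comparable),
    weight     = as.vector(weight),
    ts         = as.vector(ts),
    tv         = as.vector(tv),
    ambig      = as.vector(ambig)
  )
})

# Map a character vector/matrix of residues (already uppercased) to integer
# codes; unknown characters raise an error naming them.
encode_residues <- function(x, context = "sequence") {
  codes <- .fb_alphabet[x]
  if (anyNA(codes)) {
    bad <- sort(unique(x[is.na(codes)]))
    stop(sprintf("invalid residue character(s) in %s: %s",
                 context, paste(sQuote(bad), collapse = ", ")),
         call. = FALSE)
  }
  codes <- unname(codes)
  dim(codes) <- dim(x)
  codes
}

decode_residues <- function(codes) {
  x <- .fb_code_chars[codes]
  dim(x) <- dim(codes)
  x
}
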