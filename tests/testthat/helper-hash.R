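# Independent reference implementation of the canonical k-mer hash, written
# in pure R on 16-bit limbs (R has no native 64-bit integers). Used as the
# oracle for the compiled hash: 2-bit packing of the k-mer, XOR with the
# fixed seed, splitmix64 finalizer, canonicalization by min over strands.

u64_from_hex <- function(h) {
  h <- tolower(h)
  as.numeric(strtoi(c(substr(h, 13, 16), substr(h, 9, 12),
                      substr(h, 5, 8), substr(h, 1, 4)), 16L))
}

u64_to_hex <- function(x) sprintf("%04x%04x%04x%04x", x[4], x[3], x[2], x[1])

u64_xor <- function(a, b) as.numeric(bitwXor(as.integer(a), as.integer(b)))

u64_add <- function(a, b) {
  r <- numeric(4); carry <- 0
  for (i in 1:4) {
    s <- a[i] + b[i] + carry
    r[i] <- s %% 65536
    carry <- s %/% 65536
  }
  r
}

u64_mul <- function(a, b) {
  acc <- numeric(4)
  for (i in 1:4) for (j in 1:4) if (i + j - 1L <= 4L)
    acc[i + j - 1L] <- acc[i + j - 1L] + a[i] * b[j]
  r <- numeric(4); carry <- 0
  for (i in 1:4) {
    s <- acc[i] + carry
    r[i] <- s %% 65536
    carry <- s %/% 65536
  }
  r
}

u64_shr <- function(a, s) {
  ls <- s %/% 16L; bs <- s %% 16L
  r <- numeric(4)
  for (i in 1:4) {
    src <- i + ls
    if (src <= 4L) r[i] <- a[src] %/% 2^bs
    if (bs > 0L && src + 1L <= 4L)
      r[i] <- r[i] + (a[src + 1L] %% 2^bs) * 2^(16L - bs)
  }
  r
}

splitmix64_oracle <- function(x) {
  x <- u64_add(x, u64_from_hex("9E3779B97F4A7C15"))
  x <- u64_mul(u64_xor(x, u64_shr(x, 30L)), u64_from_hex("BF58476D1CE4E5B9"))
  x <- u64_mul(u64_xor(x, u64_shr(x, 27L)), u64_from_hex("94D049BB133111EB"))
  u64_xor(x, u64_shr(x, 31L))
}

HASH_SEED_ORACLE <- u64_from_hex("D6E8FEB86659FD93")

pack_codes_u64 <- function(codes) {
  x <- numeric(4)
  four <- c(4, 0, 0, 0)
  for (cd in codes) x <- u64_add(u64_mul(x, four), c(cd, 0, 0, 0))
  x
}

canonical_hash_oracle <- function(kmer) {
  codes <- match(strsplit(toupper(kmer), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T")) - 1L
  if (anyNA(codes)) return(list(hash = NA_character_, strand = NA_character_))
  hf <- u64_to_hex(splitmix64_oracle(
    u64_xor(pack_codes_u64(codes), HASH_SEED_ORACLE)))
  hr <- u64_to_hex(splitmix64_oracle(
    u64_xor(pack_codes_u64(rev(3L - codes)), HASH_SEED_ORACLE)))
  if (hf <= hr) list(hash = hf, strand = "+") else list(hash = hr, strand = "-")
}
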