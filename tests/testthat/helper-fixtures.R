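# small constructors shared across tests

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

qstr <- function(q) intToUtf8(q + 33L)  # Phred vector -> quality string

mk_read <- function(id, barcode, start, bases, qual = NULL) {
  if (is.null(qual)) qual <- qstr(rep(30L, nchar(bases)))
  data.frame(read_id = id, barcode = barcode, start = start,
             end = start + nchar(bases), bases = bases, qual = qual,
             stringsAsFactors = FALSE)
}

mk_reads <- function(...) do.call(rbind, list(...))

# n copies of one molecule at (start, start+nchar(bases))
mk_cluster_reads <- function(prefix, barcode, start, bases, n) {
  do.call(rbind, lapply(seq_len(n), function(k)
    mk_read(sprintf("%s_c%d", prefix, k),
            if (length(barcode) == n) barcode[k] else barcode, start, bases)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# plant fixed substitutions at given 1-based positions
plant_subs <- function(seq, pos) {
  ch <- chars(seq)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}
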