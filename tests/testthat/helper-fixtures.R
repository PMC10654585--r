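extdata <- function(f) system.file("extdata", f, package = "hostspec")

fixture_dataset <- function() {
  read_occurrence_table(extdata("molothrus_occurrence_synthetic.tsv"),
                        extdata("molothrus_hosts_synthetic.tsv"))
}

## random rooted binary tanglegram (topology only)
random_tanglegram <- function(n_host, n_symb) {
  ht <- ape::rtree(n_host, tip.label = paste0("H", seq_len(n_host)), br = NULL)
  st <- ape::rtree(n_symb, tip.label = paste0("s", seq_len(n_symb)), br = NULL)
  phi <- stats::setNames(sample(ht$tip.label, n_symb, replace = TRUE),
                         st$tip.label)
  tanglegram(ht, st, phi)
}

## independent connected-components oracle for single-linkage clustering
components_oracle <- function(m, thr) {
  n <- nrow(m)
  seen <- rep(FALSE, n)
  memb <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE; memb[v] <- comp
      queue <- c(queue, which(m[v, ] <= thr & !seen))
    }
  }
  memb
}

write_tsv_tmp <- function(df, ...) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  f
}
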