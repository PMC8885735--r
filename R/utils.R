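# Condition helper: every user-facing failure carries a machine-readable
# class ("qpcr_<code>") plus coordinates of the offending cell/gene/sample.
.qcStop <- function(code, msg, ...) {
  data <- list(...)
  cond <- errorCondition(msg,
                         class = c(paste0("qpcr_", code), "qpcrError"))
  if (length(data)) cond$data <- data
  stop(cond)
}

# Deterministic key for an (ordered) sample pair.
.pairKey <- function(a, b) paste(a, b, sep = "\t")

# Fixed float formatting so exported CSVs are byte-identical across runs.
.fmtNum <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}
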