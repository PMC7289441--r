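# Internal helpers shared across modules.

# IUPAC amino-acid one-letter codes (20 standard + B, J, O, U, X, Z).
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYBJOUXZ", "")[[1]]

is_valid_peptide_seq <- function(x) {
  !is.na(x) & nzchar(x) & grepl(paste0("^[", paste(AA_LETTERS, collapse = ""), "]+$"), x)
}

# Doubles formatted so that as.numeric() round-trips them exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

stop_contract <- function(msg, class) {
  abort(msg, class = c(class, "coprecip_error"))
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_contract(
      sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
      "coprecip_config_error"
    )
  }
  invisible(x)
}
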