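# Independent oracles and small fixtures shared across the suite.

# Naive set collection by explicit iteration over the observation list;
# deliberately avoids action_sets() so score tests have two routes.
oracle_sets <- function(cube, environment) {
  P <- character()
  D <- list()
  I <- list()
  obs <- cube$observations
  envs <- obs$environment
  orgs <- obs$organism
  mets <- obs$metabolite
  acts <- obs$action
  for (i in seq_len(nrow(obs))) {
    if (envs[i] != environment) next
    o <- orgs[i]
    m <- mets[i]
    a <- acts[i]
    if (o == control_name()) {
      if (a == "detected") P <- c(P, m)
    } else {
      if (is.null(D[[o]])) {
        D[[o]] <- character()
        I[[o]] <- character()
      }
      if (a == "decreased") D[[o]] <- c(D[[o]], m)
      if (a == "increased") I[[o]] <- c(I[[o]], m)
    }
  }
  list(P = P, D = D, I = I)
}

count_in <- function(xs, set) {
  n <- 0L
  for (x in xs) if (x %in% set) n <- n + 1L
  n
}

oracle_eus <- function(os, scored) {
  den <- length(os$P)
  num <- count_in(os$D[[scored]], os$P)
  c(num = num, den = den)
}

oracle_fmc <- function(os, scored, reference) {
  c(num = count_in(os$D[[scored]], os$D[[reference]]),
    den = length(os$D[[scored]]))
}

oracle_fme <- function(os, scored, reference) {
  c(num = count_in(os$D[[scored]], os$I[[reference]]),
    den = length(os$D[[scored]]))
}

# Welch two-sided p-value from the closed form, independent of stats::t.test.
welch_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# Small metabolite-name search fixture.
aden_cube <- function() {
  datacube(metabolites = data.frame(
    name = c("adenine", "adenosine", "methyladenosine", "glycine"),
    stringsAsFactors = FALSE))
}

# rbind observation fragments with differing optional columns.
bind_obs <- function(...) {
  dfs <- list(...)
  cols <- Reduce(union, lapply(dfs, names))
  do.call(rbind, lapply(dfs, function(d) {
    for (col in setdiff(cols, names(d))) d[[col]] <- NA
    d[cols]
  }))
}

# Upload text helper.
write_lines_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
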