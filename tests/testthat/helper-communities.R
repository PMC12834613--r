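# Fixture builders shared across test files.  All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

random_community <- function(S, T, seed) {
  set.seed(seed)
  traits <- matrix(stats::rnorm(S * T), S, T,
                   dimnames = list(paste0("sp", seq_len(S)),
                                   paste0("t", seq_len(T))))
  a <- stats::rgamma(S, shape = 2)
  list(traits = traits, p = a / sum(a))
}

# Batched scipy ConvexHull volumes: one python subprocess for a list of
# point matrices (independent oracle for the hull implementation).
scipy_hull_volumes <- function(point_sets) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(point_sets, function(P)
    unclass(as.data.frame(unname(P)))), infile, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.spatial import ConvexHull, QhullError",
    sprintf("sets = json.load(open(%s))", deparse(infile)),
    "out = []",
    "for cols in sets:",
    "    P = np.array([cols[k] for k in sorted(cols)]).T",
    "    if P.shape[1] == 1:",
    "        out.append(float(P.max() - P.min()))",
    "        continue",
    "    try:",
    "        out.append(float(ConvexHull(P).volume))",
    "    except QhullError:",
    "        out.append(0.0)",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(outfile))), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) return(NULL)
  unlist(jsonlite::read_json(outfile, simplifyVector = TRUE))
}

# replicate-biomass matrix whose per-species means are exactly `means`
biomass_with_means <- function(means, spread = 1) {
  t(vapply(means, function(m) m + spread * c(-1, 0, 1), numeric(3)))
}
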