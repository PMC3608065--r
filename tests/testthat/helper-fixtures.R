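# Shared fixture builders (all generated in code; no data files).

# Spectrum of isolated Gaussian peaks with an m/z-dependent width trend.
calibration_spectrum <- function(centers = seq(450, 1350, by = 100),
                                 sigma_fun = function(x) 0.01 + 2e-5 * x,
                                 height = 100, spacing = 0.005,
                                 mz_range = c(400, 1400)) {
  mz <- seq(mz_range[1], mz_range[2], by = spacing)
  y <- numeric(length(mz))
  for (m in centers) y <- y + height * exp(-(mz - m)^2 / (2 * sigma_fun(m)^2))
  tibble::tibble(mz = mz, intensity = y)
}

# Five disjoint patterns, charges 1-3, compact m/z window; grid-aligned
# anchors and a small constant baseline so the noiseless spectrum has a
# well-defined noise level.
noiseless_five_pattern_sim <- function() {
  pat <- data.frame(mass = c(705, 1425, 1445, 2180, 2230),
                    charge = c(1, 2, 2, 3, 3),
                    height = c(100, 80, 120, 60, 90))
  simulate_spectrum(pat, mz_range = c(695, 745), spacing = 0.02,
                    shape = list(kind = "gaussian", sigma = 0.04),
                    noise = list(baseline = 1), snap_anchors = TRUE)
}

# The hard overlap geometry: charge-2 and charge-3 peptides whose patterns
# interleave at ~351.2/351.5 Th, sampled at 0.06 Th as on a low-resolution
# ion trap, with moderate additive noise.
unmixing_sim <- function(seed, additive_sd = 0.05) {
  pat <- data.frame(sequence = c("GACLLPK", "CCTKPESER"),
                    charge = c(2, 3), height = c(100, 100))
  simulate_spectrum(pat, mz_range = c(348.5, 356), spacing = 0.06,
                    shape = list(kind = "gaussian", sigma = 0.1),
                    noise = list(additive_sd = additive_sd, baseline = 0.5),
                    seed = seed)
}

unmixing_config <- function(threshold = 1) {
  pick_config(charges = 1:4, threshold = threshold, log_level = "quiet",
              shape_params = list(kind = "gaussian", sigma = 0.1))
}

# Did the pipeline solve the overlap: both true patterns scored >= 1 and
# carrying the two largest ratios among all scored templates?
unmixing_success <- function(scores, truth) {
  sc <- scores[order(-scores$ratio), ]
  if (nrow(sc) < 2) return(FALSE)
  top2 <- sc[1:2, ]
  all(top2$ratio >= 1) &&
    any(top2$charge == truth$charge[1] &
          abs(top2$monoisotopic_mz - truth$monoisotopic_mz[1]) < 0.05) &&
    any(top2$charge == truth$charge[2] &
          abs(top2$monoisotopic_mz - truth$monoisotopic_mz[2]) < 0.05)
}

# Minimal profile-mode mzML writer (uncompressed 64-bit float arrays) used
# to exercise the mzML reading path without binary fixtures.
write_minimal_mzml <- function(mz, intensity, path) {
  enc <- function(v) gsub("\\s", "", jsonlite::base64_enc(
    writeBin(v, raw(), size = 8, endian = "little")))
  mzb <- enc(mz); inb <- enc(intensity)
  xml <- sprintf(paste0(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>\n",
    "<mzML xmlns=\"http://psi.hupo.org/ms/mzml\" version=\"1.1.0\">\n",
    "<cvList count=\"1\"><cv id=\"MS\" fullName=\"PSI-MS\" ",
    "URI=\"https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo\"/></cvList>\n",
    "<fileDescription><fileContent>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000128\" name=\"profile spectrum\" value=\"\"/>",
    "</fileContent></fileDescription>\n",
    "<run id=\"run1\">\n<spectrumList count=\"1\" defaultDataProcessingRef=\"dp1\">\n",
    "<spectrum index=\"0\" id=\"scan=1\" defaultArrayLength=\"%d\">\n",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000511\" name=\"ms level\" value=\"1\"/>\n",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000128\" name=\"profile spectrum\" value=\"\"/>\n",
    "<binaryDataArrayList count=\"2\">\n",
    "<binaryDataArray encodedLength=\"%d\">",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000514\" name=\"m/z array\" value=\"\"/>",
    "<binary>%s</binary></binaryDataArray>\n",
    "<binaryDataArray encodedLength=\"%d\">",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000576\" name=\"no compression\" value=\"\"/>",
    "<cvParam cvRef=\"MS\" accession=\"MS:1000515\" name=\"intensity array\" value=\"\"/>",
    "<binary>%s</binary></binaryDataArray>\n",
    "</binaryDataArrayList></spectrum></spectrumList></run></mzML>\n"),
    length(mz), nchar(mzb), mzb, nchar(inb), inb)
  writeLines(xml, path)
  invisible(path)
}

# Random solver instance: non-negative design, sparse non-negative target,
# additive Gaussian noise.
random_nn_instance <- function(n = 40, p = 60, k = 5, noise_sd = 0.2) {
  phi <- matrix(runif(n * p), n, p)
  beta <- rep(0, p)
  beta[sample(p, k)] <- runif(k, 0.5, 2)
  list(phi = phi, y = as.numeric(phi %*% beta) + rnorm(n, 0, noise_sd),
       beta_star = beta)
}
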