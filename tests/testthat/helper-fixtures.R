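# Shared fixtures: archetype phantoms are expensive enough to build once
# per session and reuse across tests.

.fixture_env <- new.env(parent = emptyenv())

cached_phantom <- function(type, seed = 7L) {
  key <- paste0(type, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(archetype_spec(type, seed = seed))
  .fixture_env[[key]]
}

# small hand-built label map: a sinus block, a brain block, a tumor box
tiny_map <- function(dims = c(6L, 20L, 20L), spacing = c(6, 0.45, 0.45)) {
  v <- array(0L, dim = dims)
  v[2:5, 3:16, 12:18] <- 4L              # brain, superior
  v[2:5, 8:14, 2:6] <- 3L                # sphenoid sinus, inferior
  v[3:4, 6:10, 8:14] <- 1L               # tumor above the sinus
  v[3, 9:10, 7] <- 2L                    # small pituitary
  label_map(v, spacing)
}

# a plausible 34-feature vector for scale tests, overridable per feature
make_features <- function(...) {
  f <- setNames(numeric(34), clinical_feature_names())
  f[] <- 0.5
  f["tumor_extent_ap_cm"] <- 3.0
  f["tumor_extent_si_cm"] <- 4.0
  f["tumor_extent_lr_cm"] <- 3.0
  f["pituitary_volume_cm3"] <- 0.45
  f["brain_volume_cm3"] <- 280
  f["ventricle_volume_cm3"] <- 3.0
  f["tumor_volume_cm3"] <- 15
  f["tumor_vs_brain_ap"] <- 0
  f["widest_level_fraction"] <- 0.5
  f["tumor_fossa_volume_cm3"] <- 3.0
  f["tumor_anterior_volume_cm3"] <- 0.5
  f["aspect_ratio_ap_si"] <- 0.75
  ov <- list(...)
  for (nm in names(ov)) f[nm] <- ov[[nm]]
  structure(f, missing = is.na(f), class = "clinical_features")
}

# deterministic random label mask pair for dice tests
random_mask <- function(dims, p, seed) {
  set.seed(seed)
  array(runif(prod(dims)) < p, dim = dims)
}
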