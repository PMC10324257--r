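# Shared fixtures, built programmatically and cached for the test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small noiseless, well-separated synthetic set at the tiny input size:
# 10 + 10 train, 5 + 5 test per class.
tiny_synth <- function() {
  fixture("tiny_synth", function() {
    dir <- file.path(tempdir(), "osm_fixture_synth")
    spec <- synthetic_spec(size = 64, n_per_class = 15, noise = 0, seed = 11)
    m <- generate_dataset(spec, dir)
    sp <- stratified_split(m, 2 / 3, seed = 11)
    pre <- preprocess_spec(crop = NULL, side = 64)
    list(manifest = m, split = sp, pre = pre,
         train = load_dataset(sp$train, pre),
         test = load_dataset(sp$test, pre))
  })
}

# A tiny branch trained briefly on the fixture set; enough optimization
# for the embedding space to separate the two classes.
tiny_trained <- function() {
  fixture("tiny_trained", function() {
    fx <- tiny_synth()
    net <- build_branch(branch_config("tiny"), seed = 5)
    tr <- train_model(net, fx$train,
                      train_config(learning_rate = 1e-3, batch_size = 50,
                                   epochs = 3, seed = 5),
                      loss_config(1))
    list(net = tr$net, history = tr$history,
         gallery = build_gallery(tr$net, fx$train))
  })
}

# Deterministic grayscale test raster with gradient structure.
ramp_image <- function(h = 32, w = 32, channels = 1) {
  px <- outer(seq(0, 1, length.out = h), seq(0, 1, length.out = w),
              function(a, b) (a + b) / 2)
  as_osm_image_array(array(rep(px, channels), dim = c(h, w, channels)))
}

as_osm_image_array <- function(a) a  # plain arrays are accepted by the API
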