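#!/usr/bin/env Rscript
# Command-line front end over the orchardvit package.
#
#   orchardvit datagen    --preset {afvc,afqc,adec} --out DIR --seed N
#                         [--image-size S] [--overwrite]
#   orchardvit train      --config run.yaml --data DIR [--checkpoint F]
#                         [--history F]
#   orchardvit evaluate   --checkpoint F --data DIR [--split test] [--json F]
#   orchardvit cv         --config run.yaml --data DIR --folds K
#   orchardvit imbalance  --classes N --majority N --minority N --seeds K
#                         [--epochs N] [--out F]
#   orchardvit losscurves --loss {ce,focal,mfce} [--gamma G,...] [--dv D,...]
#                         [--grid-points N] --out curves.csv

suppressPackageStartupMessages(library(orchardvit))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0) stop("no subcommand given; see the script header")
cmd <- argv[1]
argv <- argv[-1]
opt <- function(flag, default = NULL) {
  i <- match(flag, argv)
  if (is.na(i)) return(default)
  if (i == length(argv) || startsWith(argv[i + 1], "--")) return(TRUE)
  argv[i + 1]
}
num_list <- function(x) as.numeric(strsplit(x, ",")[[1]])

switch(cmd,
  datagen = {
    design <- design_presets(opt("--preset", "afqc"),
                             image_size = as.integer(opt("--image-size", 96)))
    m <- generate_dataset(design, opt("--out", "dataset"),
                          master_seed = as.integer(opt("--seed", 1)),
                          overwrite = isTRUE(opt("--overwrite", FALSE)))
    cat("generated", nrow(m), "images under", opt("--out", "dataset"), "\n")
  },
  train = {
    cfg <- read_run_config(opt("--config"))
    run <- oaom_train(cfg$model_config, opt("--data", cfg$data$dir),
                      cfg$train_cfg, checkpoint = opt("--checkpoint"))
    hist_path <- opt("--history")
    if (!is.null(hist_path)) write_history(run, hist_path)
    print(run)
  },
  evaluate = {
    rep <- evaluate(opt("--checkpoint"), opt("--data"),
                    split = opt("--split", "test"))
    print(rep)
    json_path <- opt("--json")
    if (!is.null(json_path)) report_to_json(rep, json_path)
  },
  cv = {
    cfg <- read_run_config(opt("--config"))
    cfg$train_cfg$kfold <- as.integer(opt("--folds", 10))
    cv <- kfold_cv(cfg$model_config, opt("--data", cfg$data$dir),
                   cfg$train_cfg)
    print(cv$summary, row.names = FALSE)
  },
  imbalance = {
    design <- imbalance_design(as.integer(opt("--classes", 2)),
                               as.integer(opt("--majority", 95)),
                               as.integer(opt("--minority", 5)))
    tc <- train_config(epochs = as.integer(opt("--epochs", 30)),
                       batch_size = 16,
                       loss_params = loss_params(gamma = 2, dv = 1))
    tab <- imbalance_experiment(design, c("ce", "mfce"),
                                seeds = seq_len(as.integer(opt("--seeds", 5))),
                                train_cfg = tc)
    out <- opt("--out")
    if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
    print(tab, row.names = FALSE)
  },
  losscurves = {
    tab <- loss_curve(opt("--loss", "mfce"),
                      gamma_values = num_list(opt("--gamma", "2")),
                      dv_values = num_list(opt("--dv", "1")),
                      grid = seq(0.001, 0.999,
                                 length.out = as.integer(opt("--grid-points",
                                                             999))))
    write.csv(tab, opt("--out", "curves.csv"), row.names = FALSE)
    cat("wrote", nrow(tab), "rows\n")
  },
  stop("unknown subcommand: ", cmd)
)
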