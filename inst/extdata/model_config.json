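{
  "objective": "binary:logistic",
  "min_child_weight": 10,
  "early_stopping_rounds": 10,
  "nrounds": 100,
  "eta": 0.3,
  "max_depth": 6,
  "subsample": 1.0,
  "colsample_bytree": 1.0,
  "lambda": 1.0,
  "alpha": 0.0,
  "gamma": 0.0,
  "nthread": 1
}
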