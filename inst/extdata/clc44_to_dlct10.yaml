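source_classes:
- code: 111
  name: source_111
- code: 112
  name: source_112
- code: 121
  name: source_121
- code: 122
  name: source_122
- code: 123
  name: source_123
- code: 124
  name: source_124
- code: 131
  name: source_131
- code: 132
  name: source_132
- code: 133
  name: source_133
- code: 141
  name: source_141
- code: 142
  name: source_142
- code: 211
  name: source_211
- code: 212
  name: source_212
- code: 213
  name: source_213
- code: 221
  name: source_221
- code: 222
  name: source_222
- code: 223
  name: source_223
- code: 241
  name: source_241
- code: 242
  name: source_242
- code: 243
  name: source_243
- code: 244
  name: source_244
- code: 231
  name: source_231
- code: 321
  name: source_321
- code: 311
  name: source_311
- code: 312
  name: source_312
- code: 313
  name: source_313
- code: 322
  name: source_322
- code: 323
  name: source_323
- code: 324
  name: source_324
- code: 331
  name: source_331
- code: 332
  name: source_332
- code: 333
  name: source_333
- code: 334
  name: source_334
- code: 335
  name: source_335
- code: 411
  name: source_411
- code: 412
  name: source_412
- code: 421
  name: source_421
- code: 422
  name: source_422
- code: 423
  name: source_423
- code: 511
  name: source_511
- code: 512
  name: source_512
- code: 521
  name: source_521
- code: 522
  name: source_522
- code: 523
  name: source_523
dlct_classes:
- code: 1
  name: artificial
- code: 2
  name: arable
- code: 3
  name: pasture_grassland
- code: 4
  name: permanent_crops
- code: 5
  name: forest
- code: 6
  name: transitional_woodland_shrub
- code: 7
  name: sparse_bare
- code: 8
  name: wetland
- code: 9
  name: water_body
- code: 10
  name: glacier_snow
mapping:
  '111': 1
  '112': 1
  '121': 1
  '122': 1
  '123': 1
  '124': 1
  '131': 1
  '132': 1
  '133': 1
  '141': 1
  '142': 1
  '211': 2
  '212': 2
  '213': 2
  '221': 4
  '222': 4
  '223': 4
  '241': 4
  '242': 4
  '243': 4
  '244': 4
  '231': 3
  '321': 3
  '311': 5
  '312': 5
  '313': 5
  '322': 6
  '323': 6
  '324': 6
  '331': 7
  '332': 7
  '333': 7
  '334': 7
  '335': 10
  '411': 8
  '412': 8
  '421': 8
  '422': 8
  '423': 8
  '511': 9
  '512': 9
  '521': 9
  '522': 9
  '523': 9
green_weight:
  '1': 0.0
  '2': 0.3
  '3': 0.6
  '4': 0.5
  '5': 1.0
  '6': 0.8
  '7': 0.2
  '8': 0.9
  '9': 0.8
  '10': 0.1
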