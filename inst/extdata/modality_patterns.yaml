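# Drug-name -> contraceptive-modality pattern table.
# Matching is case-insensitive regex. `exclude` patterns are tested first
# (non-drug contraceptives and emergency contraception are removed from the
# cohort, not mapped). Within `modalities`, classes are tested in the order
# listed and the first pattern that fires wins. Users may edit or extend this
# file and pass it wherever a `patterns` argument is accepted.
exclude:
  - "emergency"
  - "\\bplan ?b\\b"
  - "\\bella\\b"
  - "ulipristal"
  - "condom"
  - "diaphragm"
  - "cervical cap"
  - "spermicide"
  - "nonoxynol"
  - "ph modulator"
  - "lactic acid.*citric"
  - "phexxi"
modalities:
  Implant:
    - "etonogestrel.*implant"
    - "nexplanon"
    - "implanon"
    - "subdermal"
    - "\\bimplant\\b"
  IUD:
    - "\\biud\\b"
    - "intrauterine"
    - "mirena"
    - "kyleena"
    - "liletta"
    - "skyla"
    - "paragard"
    - "levonorgestrel.*(52|19\\.5|13\\.5) ?mg"
  Injectable:
    - "depo.?provera"
    - "medroxyprogesterone"
    - "\\bdepot?\\b"
    - "injectab|\\binjection\\b|\\bintramuscular\\b|\\bsubcutaneous\\b"
  Transdermal:
    - "transdermal"
    - "\\bpatch\\b"
    - "xulane"
    - "twirla"
    - "ortho ?evra"
  Intravaginal:
    - "intravaginal|vaginal ring"
    - "nuvaring"
    - "annovera"
    - "eluryng"
    - "\\bring\\b"
  Oral:
    - "\\boral\\b|\\btablet\\b|\\bpills?\\b"
    - "norethindrone"
    - "camila"
    - "heather"
    - "errin"
    - "sprintec"
    - "yaz\\b|yasmin"
    - "loestrin|junel"
    - "drospirenone"
    - "norgestimate"
    - "desogestrel"
    - "levonorgestrel.*ethinyl"
    - "\\bocps?\\b"
    - "birth control pill"
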