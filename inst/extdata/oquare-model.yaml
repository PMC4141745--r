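# Default quality model: 12 structural metrics -> 29 subcharacteristics
# -> 7 characteristics.
#
# The aggregation mechanism (threshold bands mapping each metric onto the
# 1-5 scale, then weighted averages upwards) is fixed; the constants in
# this file are a documented reconstruction and every entry can be
# overridden by loading a modified copy with readQualityModel().
# Anchors used for the metric assignments: annotation richness feeds
# Knowledge Reuse, Redundancy and Controlled Vocabulary; multiple
# parenthood (NOCOnto/NACOnto) feeds Tangledness; path cohesion
# (LCOMOnto) feeds Cohesion and Modularity.  Weights are equal within
# each aggregation level (a bare list means equal weights; a mapping
# gives explicit weights, normalized at load time).
#
# direction: higher = larger raw values score better; lower = smaller
# raw values score better.  bands: four strictly increasing cut points;
# for "higher" metrics, value < b1 scores 1 and value >= b4 scores 5,
# with half-open bands [b_i, b_{i+1}) in between; "lower" metrics use
# the mirror image.

metrics:
  LCOMOnto: {direction: lower,  bands: [2, 4, 6, 8]}
  WMCOnto:  {direction: lower,  bands: [3, 6, 9, 12]}
  DITOnto:  {direction: lower,  bands: [2, 4, 6, 8]}
  NACOnto:  {direction: higher, bands: [1.05, 1.15, 1.3, 1.5]}
  NOCOnto:  {direction: lower,  bands: [1.1, 1.3, 1.6, 2.0]}
  RFCOnto:  {direction: lower,  bands: [0.5, 1, 2, 3]}
  NOMOnto:  {direction: lower,  bands: [0.5, 1, 2, 3]}
  PROnto:   {direction: higher, bands: [0.15, 0.3, 0.45, 0.6]}
  AROnto:   {direction: higher, bands: [0.25, 0.5, 0.75, 1.0]}
  INROnto:  {direction: higher, bands: [0.5, 0.65, 0.8, 0.9]}
  CROnto:   {direction: higher, bands: [0.25, 0.5, 0.75, 1.0]}
  ANOnto:   {direction: higher, bands: [0.2, 0.4, 0.6, 0.8]}

subcharacteristics:
  Reference Ontology: [PROnto]
  Text Analysis: [PROnto]
  Infering: [PROnto]
  Formalisation: [PROnto]
  Formal Relation Support: [PROnto]
  Consistency: [PROnto]
  Schema And Value Reconciliation: [RFCOnto]
  Indexing And Linking: [CROnto, RFCOnto]
  Clustering And Similarity: [CROnto, AROnto]
  Guidance And Decision Trees: [NACOnto, DITOnto]
  Results Representation: [WMCOnto, AROnto]
  Knowledge Reuse: [ANOnto]
  Tangledness: [NOCOnto, NACOnto]
  Modularity: [LCOMOnto, WMCOnto]
  Knowledge Acquisition: [INROnto, NOMOnto]
  Modification Stability: [NOCOnto, DITOnto]
  Learnability: [DITOnto, WMCOnto, LCOMOnto]
  Reusability: [NOMOnto, RFCOnto, WMCOnto]
  Changeability: [NOCOnto, WMCOnto, LCOMOnto]
  Availability: [NOCOnto, RFCOnto]
  Cohesion: [LCOMOnto]
  Analysability: [WMCOnto, RFCOnto, DITOnto]
  Testability: [WMCOnto, RFCOnto, DITOnto]
  Adaptability: [DITOnto, NOCOnto, INROnto]
  Consistent Search And Query: [RFCOnto, CROnto]
  Replaceability: [WMCOnto, NOMOnto]
  Recoverability: [LCOMOnto, NOCOnto]
  Controlled Vocabulary: [ANOnto]
  Redundancy: [ANOnto]

characteristics:
  Structural: [Formalisation, Formal Relation Support, Cohesion,
               Tangledness, Redundancy, Consistency]
  Functional Adequacy: [Reference Ontology, Controlled Vocabulary,
                        Schema And Value Reconciliation,
                        Consistent Search And Query,
                        Knowledge Acquisition, Clustering And Similarity,
                        Indexing And Linking, Results Representation,
                        Text Analysis, Guidance And Decision Trees,
                        Knowledge Reuse, Infering]
  Compatibility: [Replaceability]
  Transferability: [Adaptability]
  Operability: [Learnability]
  Maintainability: [Modularity, Reusability, Analysability,
                    Changeability, Modification Stability, Testability]
  Reliability: [Availability, Recoverability]
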