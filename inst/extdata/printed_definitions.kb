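# Reference class definitions of the bone dysplasia knowledge model:
# the top-level concepts (Bone_Dysplasia, Gene_Mutation,
# Phenotypic_Composite) and the worked instances (Achondroplasia,
# GM0000001, PC_0000004/AC_0000001, PC_0000005/QC_0000001), together with
# the minimal external term references and support classes they mention.

Ontology:
  dc:title "Bone dysplasia knowledge model: reference definitions"
  dc:creator "bdokit"
  dc:contributor ""
  dc:publisher ""
  version "1.5"

ExternalTerm: FMA:Anatomical_entity
  Source: FMA
  Label: "Anatomical entity"

ExternalTerm: FMA:Femur
  Source: FMA
  Label: "Femur"
  Parent: FMA:Anatomical_entity

ExternalTerm: FMA:Primary_anatomical_coordinate
  Source: FMA
  Label: "Primary anatomical coordinate"

ExternalTerm: FMA:Proximal
  Source: FMA
  Label: "Proximal"
  Parent: FMA:Primary_anatomical_coordinate

ExternalTerm: HP:HP_0000005
  Source: HP
  Label: "Mode of inheritance"

ExternalTerm: HP:HP_0000006
  Source: HP
  Label: "Autosomal dominant inheritance"
  Parent: HP:HP_0000005

ExternalTerm: HP:HP_0000118
  Source: HP
  Label: "Phenotypic abnormality"

ExternalTerm: HP:HP_0000238
  Source: HP
  Label: "Hydrocephalus"
  Parent: HP:HP_0000118

ExternalTerm: HP:HP_0002938
  Source: HP
  Label: "Lumbar hyperlordosis"
  Parent: HP:HP_0000118

ExternalTerm: HP:HP_0002968
  Source: HP
  Label: "Phenotypic feature 0002968"
  Parent: HP:HP_0000118

ExternalTerm: HP:HP_0003505
  Source: HP
  Label: "Phenotypic feature 0003505"
  Parent: HP:HP_0000118

ExternalTerm: NCI:Missense_Mutation
  Source: NCI
  Label: "Missense mutation"
  Parent: NCI:Mutation_Abnormality

ExternalTerm: NCI:Mutation_Abnormality
  Source: NCI
  Label: "Mutation abnormality"

ExternalTerm: PATO:PATO_0000068
  Source: PATO
  Label: "Qualitative"

ExternalTerm: PATO:PATO_0000947
  Source: PATO
  Label: "Oval"
  Parent: PATO:PATO_0000068

ExternalTerm: PATO:PATO_0001241
  Source: PATO
  Label: "Physical object quality"

ExternalTerm: PATO:PATO_0001354
  Source: PATO
  Label: "Translucent"
  Parent: PATO:PATO_0001241

ExternalTerm: REAMS:Abnormality
  Source: REAMS
  Label: "Radiographic abnormality"

Class: Bone_Dysplasia
  Pillar: dysplasia
  Label: "Bone Dysplasia"
  Description: "A genetic disorder that involves abnormal development of bones and connective tissues."
  SubClassOf: characterized_by only (REAMS:Abnormality or HP:HP_0000118 or Phenotypic_Composite or Gene_Mutation)
  SubClassOf: mode_of_inheritance only HP:HP_0000005

Class: Gene
  Pillar: gene
  Label: "Gene"

Class: Gene_Mutation
  Pillar: gene_mutation
  Label: "Gene Mutation"
  Description: "A change or alteration in a gene."
  SubClassOf: has_locus only Gene and has_locus some Gene
  SubClassOf: mutation_type only NCI:Mutation_Abnormality and mutation_type some NCI:Mutation_Abnormality

Class: Protein
  Pillar: protein
  Label: "Protein"

Class: Phenotypic_Composite
  Pillar: phenotypic_composite
  Label: "Phenotypic Composite"
  Description: "A continuant describing the conjunction between a quality and an anatomical part or an anatomical composite."
  SubClassOf: (has_part some Phenotypic_Composite and has_part only Phenotypic_Composite) or (describes some FMA:Anatomical_entity and describes only FMA:Anatomical_entity) or (describes some Anatomical_Composite and describes only Anatomical_Composite)
  SubClassOf: (has_quality only PATO:PATO_0001241 and has_quality some PATO:PATO_0001241) or (has_quality only Quality_Composite and has_quality some Quality_Composite)

Class: Anatomical_Composite
  Pillar: anatomical_composite
  Label: "Anatomical Composite"

Class: Quality_Composite
  Pillar: quality_composite
  Label: "Quality Composite"

Class: Achondroplasia
  Pillar: dysplasia
  Label: "Achondroplasia"
  Parent: Bone_Dysplasia
  SubClassOf: characterized_by only (GM0000001 or GM0000361 or HP:HP_0000238 or HP:HP_0002938 or HP:HP_0002968 or HP:HP_0003505)
  SubClassOf: mode_of_inheritance only HP:HP_0000006 and mode_of_inheritance some HP:HP_0000006

Class: G0000001
  Pillar: gene
  Label: "FGFR3"
  Parent: Gene

Class: GM0000001
  Pillar: gene_mutation
  Label: "GM0000001"
  Parent: Gene_Mutation
  SubClassOf: has_locus only G0000001 and has_locus some G0000001
  SubClassOf: mutation_type only NCI:Missense_Mutation and mutation_type some NCI:Missense_Mutation
  Annotation: encoding "GLY380ARG, 1138 G-A"
  Annotation: offset "1138"
  Annotation: count "1"
  Annotation: original_content "G"
  Annotation: mutated_content "A"

Class: GM0000361
  Pillar: gene_mutation
  Label: "GM0000361"
  Parent: Gene_Mutation
  SubClassOf: has_locus only G0000001 and has_locus some G0000001
  SubClassOf: mutation_type only NCI:Missense_Mutation and mutation_type some NCI:Missense_Mutation

Class: AC_0000001
  Pillar: anatomical_composite
  Label: "Proximal femur"
  Description: "The proximal area of the femur"
  Parent: Anatomical_Composite
  SubClassOf: has_part only FMA:Femur and has_part some FMA:Femur
  SubClassOf: has_anatomical_coordinate only FMA:Proximal and has_anatomical_coordinate some FMA:Proximal

Class: QC_0000001
  Pillar: quality_composite
  Label: "Oval translucency"
  Description: "Oval-shaped area of translucency"
  Parent: Quality_Composite
  SubClassOf: has_part only PATO:PATO_0001354 and has_part some PATO:PATO_0001354
  SubClassOf: has_qualifier only PATO:PATO_0000947 and has_qualifier some PATO:PATO_0000947

Class: PC_0000004
  Pillar: phenotypic_composite
  Label: "Translucency of proximal femur"
  Description: "Translucent proximal area of femur"
  Parent: Phenotypic_Composite
  SubClassOf: describes only AC_0000001 and describes some AC_0000001
  SubClassOf: has_quality only PATO:PATO_0001354 and has_quality some PATO:PATO_0001354

Class: PC_0000005
  Pillar: phenotypic_composite
  Label: "Oval translucency of proximal femur"
  Description: "Oval-shaped translucent area of the proximal femur"
  Parent: Phenotypic_Composite
  SubClassOf: describes only AC_0000001 and describes some AC_0000001
  SubClassOf: has_quality only QC_0000001 and has_quality some QC_0000001
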