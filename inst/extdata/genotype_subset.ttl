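# Genotype subset fixture, Turtle serialization.
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix skos: <http://www.w3.org/2004/02/skos/core#> .
@prefix dc: <http://purl.org/dc/terms/> .
@prefix bdo: <http://purl.org/skeletome/bonedysplasia#> .
@prefix hp: <http://purl.org/obo/owl/HP#> .
@prefix nci: <http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#> .
@prefix reams: <http://d-reams.org/ontology#> .

<http://purl.org/skeletome/bonedysplasia> a owl:Ontology ;
    dc:title "Bone dysplasia knowledge model: genotype subset" ;
    dc:creator "bdokit" ;
    owl:versionInfo "1.5" .

hp:HP_0000005 a owl:Class ;
    rdfs:label "Mode of inheritance" .

hp:HP_0000006 a owl:Class ;
    rdfs:label "Autosomal dominant inheritance" ;
    rdfs:subClassOf hp:HP_0000005 .

hp:HP_0000118 a owl:Class ;
    rdfs:label "Phenotypic abnormality" .

hp:HP_0000238 a owl:Class ;
    rdfs:label "Hydrocephalus" ;
    rdfs:subClassOf hp:HP_0000118 .

hp:HP_0002938 a owl:Class ;
    rdfs:label "Lumbar hyperlordosis" ;
    rdfs:subClassOf hp:HP_0000118 .

hp:HP_0002968 a owl:Class ;
    rdfs:label "Phenotypic feature 0002968" ;
    rdfs:subClassOf hp:HP_0000118 .

hp:HP_0003505 a owl:Class ;
    rdfs:label "Phenotypic feature 0003505" ;
    rdfs:subClassOf hp:HP_0000118 .

nci:Mutation_Abnormality a owl:Class ;
    rdfs:label "Mutation abnormality" .

nci:Missense_Mutation a owl:Class ;
    rdfs:label "Missense mutation" ;
    rdfs:subClassOf nci:Mutation_Abnormality .

reams:Abnormality a owl:Class ;
    rdfs:label "Radiographic abnormality" .

bdo:Bone_Dysplasia a owl:Class ;
    rdfs:label "Bone Dysplasia" ;
    skos:description "A genetic disorder that involves abnormal development of bones and connective tissues." ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:characterized_by ;
        owl:allValuesFrom [ a owl:Class ;
            owl:unionOf ( reams:Abnormality hp:HP_0000118 bdo:Phenotypic_Composite bdo:Gene_Mutation ) ] ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mode_of_inheritance ;
        owl:allValuesFrom hp:HP_0000005 ] .

bdo:Gene_Mutation a owl:Class ;
    rdfs:label "Gene Mutation" ;
    skos:description "A change or alteration in a gene." ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:has_locus ;
        owl:allValuesFrom bdo:Gene ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:has_locus ;
        owl:someValuesFrom bdo:Gene ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mutation_type ;
        owl:allValuesFrom nci:Mutation_Abnormality ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mutation_type ;
        owl:someValuesFrom nci:Mutation_Abnormality ] .

bdo:Achondroplasia a owl:Class ;
    rdfs:label "Achondroplasia" ;
    rdfs:subClassOf bdo:Bone_Dysplasia ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:characterized_by ;
        owl:allValuesFrom [ a owl:Class ;
            owl:unionOf ( bdo:GM0000001 bdo:GM0000361 hp:HP_0000238 hp:HP_0002938 hp:HP_0002968 hp:HP_0003505 ) ] ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mode_of_inheritance ;
        owl:allValuesFrom hp:HP_0000006 ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mode_of_inheritance ;
        owl:someValuesFrom hp:HP_0000006 ] .

bdo:G0000001 a owl:Class ;
    rdfs:label "FGFR3" ;
    rdfs:subClassOf bdo:Gene .

bdo:GM0000001 a owl:Class ;
    rdfs:label "GM0000001" ;
    rdfs:subClassOf bdo:Gene_Mutation ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:has_locus ;
        owl:allValuesFrom bdo:G0000001 ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:has_locus ;
        owl:someValuesFrom bdo:G0000001 ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mutation_type ;
        owl:allValuesFrom nci:Missense_Mutation ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mutation_type ;
        owl:someValuesFrom nci:Missense_Mutation ] ;
    bdo:encoding "GLY380ARG, 1138 G-A" ;
    bdo:offset "1138" ;
    bdo:count "1" ;
    bdo:original_content "G" ;
    bdo:mutated_content "A" .

bdo:GM0000361 a owl:Class ;
    rdfs:label "GM0000361" ;
    rdfs:subClassOf bdo:Gene_Mutation ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:has_locus ;
        owl:allValuesFrom bdo:G0000001 ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:has_locus ;
        owl:someValuesFrom bdo:G0000001 ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mutation_type ;
        owl:allValuesFrom nci:Missense_Mutation ] ;
    rdfs:subClassOf [ a owl:Restriction ;
        owl:onProperty bdo:mutation_type ;
        owl:someValuesFrom nci:Missense_Mutation ] .
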