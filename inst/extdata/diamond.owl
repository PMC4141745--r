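<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Ontology rdf:about="http://example.org/diamond"/>
  <owl:Class rdf:about="http://example.org/diamond#A"/>
  <owl:Class rdf:about="http://example.org/diamond#B">
    <rdfs:subClassOf rdf:resource="http://example.org/diamond#A"/>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/diamond#C">
    <rdfs:subClassOf rdf:resource="http://example.org/diamond#A"/>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/diamond#D">
    <rdfs:subClassOf rdf:resource="http://example.org/diamond#B"/>
    <rdfs:subClassOf rdf:resource="http://example.org/diamond#C"/>
  </owl:Class>
</rdf:RDF>
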