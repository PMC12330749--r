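[{"CXVersion":"2.0","hasFragments":false},{"attributeDeclarations":[{"networkAttributes":{"name":{"d":"string"},"sources":{"d":"list_of_string"},"generated_by":{"d":"string"}},"nodes":{"name":{"d":"string"},"bel":{"d":"string"},"namespace":{"d":"string"},"identifier":{"d":"string"}},"edges":{"interaction":{"d":"string"},"bel":{"d":"string"},"evidence":{"d":"list_of_string"},"source":{"d":"list_of_string"},"paragraph":{"d":"list_of_long"}}}]},{"networkAttributes":[{"name":"golden two-node network","sources":["PMC0000001"],"generated_by":"beltograph"}]},{"nodes":[{"id":0,"v":{"name":"AKT1","bel":"p(HGNC:AKT1)","namespace":"HGNC","identifier":"AKT1"}},{"id":1,"v":{"name":"HSF1","bel":"p(HGNC:HSF1)","namespace":"HGNC","identifier":"HSF1"}}]},{"edges":[{"id":0,"s":0,"t":1,"v":{"interaction":"increases","bel":"p(HGNC:AKT1) increases p(HGNC:HSF1)","evidence":["AKT1 increases HSF1 levels."],"source":["PMC0000001"],"paragraph":[0]}}]},{"status":[{"success":true}]}]
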