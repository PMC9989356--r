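species	lineage	class
Acropora	Anthozoa	Hexacorallia
Stylophora	Anthozoa	Hexacorallia
Exaiptasia	Anthozoa	Hexacorallia
Nematostella	Anthozoa	Hexacorallia
Renilla	Anthozoa	Octocorallia
Rhopilema	Medusozoa	Scyphozoa
Sanderia	Medusozoa	Scyphozoa
Hydra	Medusozoa	Hydrozoa
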