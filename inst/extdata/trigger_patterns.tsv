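my daughter	following	relation
my son	following	relation
my wife	following	relation
my husband	following	relation
my mother	following	relation
my father	following	relation
my sister	following	relation
my brother	following	relation
my uncle	following	relation
my aunt	following	relation
an uncle of	following	relation
an aunt of	following	relation
my name is	following	self_id
sincerely	following	self_id
yours truly	following	self_id
regards	following	self_id
was born	preceding	life_event
were married	preceding	life_event
died in	preceding	life_event
passed away	preceding	life_event
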