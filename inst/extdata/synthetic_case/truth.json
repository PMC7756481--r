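{"key":"chr17:39855064:G:C","gene":"GENE0010","disease_id":"DIS:0004","consequence":"stop_gained","zygosity":"het","patient_terms":["HP:0000037","HP:0000006","HP:0000032","HP:0000008","HP:0000025","HP:0000012"],"seed":2026}
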