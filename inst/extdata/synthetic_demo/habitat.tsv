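id	habitat
marine1	marine
marine2	marine
fresh1	freshwater
fresh2	freshwater
fresh3	freshwater
fresh4	freshwater
fresh5	freshwater
fresh6	freshwater
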