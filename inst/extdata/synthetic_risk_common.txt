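# Synthetic stand-in list: 16 common-variant epilepsy risk genes (CVG* placeholders).
CVG001
CVG002
CVG003
CVG004
CVG005
CVG006
CVG007
CVG008
CVG009
CVG010
CVG011
CVG012
CVG013
CVG014
CVG015
CVG016
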