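>marine1 synthetic AAR-like sequence
APRDARWTIYSQWFDVMVGIEAPHYATGQIDMHVHVLINGVGDSYDIEFAGISFAFISCS
LKTLWKGRIDCQVWLMQENKACLKQANFGMKWCIAVEYLLPENIPPFWTIGTLVHVDIAV
>marine2 synthetic AAR-like sequence
APRDARWTIVSQWFDVMVGIEAPHYATGQIDMHVHILIYMVGDSYDIEFAGISFAYISCS
LKTLWKGRYDCQVWLMQENKACLKQANFGMKWCIAVEYLEPENIPPFWTIGTLVHVDITV
>fresh1 synthetic AAR-like sequence
ACRDARWTIYSQWFDVMVGREAPHYATGKIDMEVHVLYYMQGDSFDFEFAGISFAFISCS
LWALWKCRIDCQVLLMQENKACLKQANFGMKWCMAVECLEPENIPPIWTIGTLVNSDITV
>fresh2 synthetic AAR-like sequence
ACRDARWTIYSQWFDVMVGICAPHYDTGKHDMHVHVLKYWQGDSLDIEFAGISFAFISCK
LTALWKCRIDCQVWLMQENKACHKQANFGMKWCMAVECLEPENIPPIWTIGTLVHVDILV
>fresh3 synthetic AAR-like sequence
ACRDARWTIYSQWFDVMVGIEAPHYATGYIDMHVHVLYYMQGDSLDIEFAGISFAFISCS
LWALWKCRIDCQVWLMQENKACLKQANFGMKWCMAVECLEPENIPPYWTIGTLVHVDITV
>fresh4 synthetic AAR-like sequence
ACRDARWTIYSQWFDVMVGIEAPHYATGYIDMHVHVLKYMQGDSFDIEFAGISEAFISCS
LWALWKCRIDCQVWLMQEQKACLKWANFGWKWCMAVECLEPENSPPYWTIGFLVHVDITV
>fresh5 synthetic AAR-like sequence
AFRDARWTIYSQWFDVMVGIEAPHYATGKIEMHVHVLYYMQGCSLDIEFAGISFAFISCS
LWALWKCRIDCQVWLMQENKACLKQANFGMKVCMAVEALEPENSPPIWTLGTLVHVDITV
>fresh6 synthetic AAR-like sequence
AFRDARWTIYSQWFDVMVGIEAPHYATGKIDMHVHVLKYHQGRSFDIEFAGISFAFISCS
ITALWKCRIDCQVWLMQENQACLKQANFGMKWCMAVWCCEPENIPPIWTIGTLVHVGITV
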