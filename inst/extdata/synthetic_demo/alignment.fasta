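>marine1
APRDARWTIYSQWFDVMVGIEAPHYATGQIDMHVHVLINGVGDSYDIEFAGISFAFISCS
LKTLWKGRIDCQVWLMQENKACLKQANFGMKWCIAVEYLLPENIPPFWTIGTLVHVDIAV
>marine2
APRDARWTIVSQWFDVMVGIEAPHYATGQIDMHVHILIYMVGDSYDIEFAGISFAYISCS
LKTLWKGRYDCQVWLMQENKACLKQANFGMKWCIAVEYLEPENIPPFWTIGTLVHVDITV
>fresh1
ACRDARWTIYSQWFDVMVGREAPHYATGKIDMEVHVLYYMQGDSFDFEFAGISFAFISCS
LWALWKCRIDCQVLLMQENKACLKQANFGMKWCMAVECLEPENIPPIWTIGTLVNSDITV
>fresh2
ACRDARWTIYSQWFDVMVGICAPHYDTGKHDMHVHVLKYWQGDSLDIEFAGISFAFISCK
LTALWKCRIDCQVWLMQENKACHKQANFGMKWCMAVECLEPENIPPIWTIGTLVHVDILV
>fresh3
ACRDARWTIYSQWFDVMVGIEAPHYATGYIDMHVHVLYYMQGDSLDIEFAGISFAFISCS
LWALWKCRIDCQVWLMQENKACLKQANFGMKWCMAVECLEPENIPPYWTIGTLVHVDITV
>fresh4
ACRDARWTIYSQWFDVMVGIEAPHYATGYIDMHVHVLKYMQGDSFDIEFAGISEAFISCS
LWALWKCRIDCQVWLMQEQKACLKWANFGWKWCMAVECLEPENSPPYWTIGFLVHVDITV
>fresh5
AFRDARWTIYSQWFDVMVGIEAPHYATGKIEMHVHVLYYMQGCSLDIEFAGISFAFISCS
LWALWKCRIDCQVWLMQENKACLKQANFGMKVCMAVEALEPENSPPIWTLGTLVHVDITV
>fresh6
AFRDARWTIYSQWFDVMVGIEAPHYATGKIDMHVHVLKYHQGRSFDIEFAGISFAFISCS
ITALWKCRIDCQVWLMQENQACLKQANFGMKWCMAVWCCEPENIPPIWTIGTLVHVGITV
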