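# criteria for selecting digital tools used in telepharmacy
- area: Integration
  description: Integration into health information systems
- area: Maintenance
  description: Guaranteed maintenance
- area: Training
  description: Appropriate training plan for staff involved in this service
- area: Proactive risk assessment
  description: Risk mitigation strategies (damaged equipment, helpdesks,
    software protection, virus protocols, hacking)
- area: Update
  description: Plan for periodic reassessment of technology solutions
    available on the market and their suitability for the clinical objective
- area: User experience
  description: Plan to periodically evaluate the experience of users
    (professionals and patients) and implement the improvements detected
- area: Support service
  description: Plan for user support, training and resolution of doubts
    and incidents
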